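# Cross-variant diversification analysis of one DGR over multiple
# lysogens: TR invariance, a census of variable positions, their adenine
# specificity, codon context (asparagine codons), and the exact size of
# the explorable sequence space.

#' Create a variant set
#'
#' One DGR observed across several lysogens: the TR consensus plus one VR
#' per tropic variant, all the same length (repeats are compared gaplessly
#' column by column; a length mismatch is an error, never silently aligned).
#'
#' @param dgr_id Identifier.
#' @param tr_consensus TR DNA string.
#' @param vrs Named character vector or list of VR strings (names = variant
#'   ids), each the same length as the TR.
#' @param reading_frame Optional list `list(offset = 0/1/2, strand = "+"/"-")`
#'   giving the frame of the VR within its target ORF; needed for the
#'   asparagine-codon fraction.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(dgr_id, tr_consensus, vrs, reading_frame = NULL) {
  tr_consensus <- toupper(tr_consensus)
  vrs <- lapply(vrs, toupper)
  if (is.null(names(vrs)) || any(!nzchar(names(vrs))))
    names(vrs) <- sprintf("variant%d", seq_along(vrs))
  if (any(nchar(unlist(vrs)) != nchar(tr_consensus)))
    stop("variant_set: all VRs must match the TR length")
  if (!is.null(reading_frame)) {
    stopifnot(reading_frame$offset %in% 0:2,
              reading_frame$strand %in% c("+", "-"))
  }
  structure(list(dgr_id = dgr_id, tr_consensus = tr_consensus,
                 vrs = vrs, reading_frame = reading_frame),
            class = "variant_set")
}

#' Check template-repeat invariance across lysogens
#'
#' The TR is the donor copy and should be identical in every lysogen;
#' diversification appears only in the VR.
#'
#' @param trs Character vector/list of equal-length TR strings.
#' @return List with `invariant` (logical) and `columns` (0-based indices
#'   of discordant columns; empty when invariant).
#' @export
check_tr_invariance <- function(trs) {
  trs <- toupper(unlist(trs))
  if (length(unique(nchar(trs))) > 1L)
    stop("check_tr_invariance: TRs must have equal lengths")
  if (length(trs) <= 1L) return(list(invariant = TRUE, columns = integer(0)))
  mat <- do.call(rbind, strsplit(trs, "", fixed = TRUE))
  discordant <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  list(invariant = length(discordant) == 0L, columns = discordant - 1L)
}

#' Diversification report for a variant set
#'
#' Census of variable positions (columns where any VR differs from the TR;
#' columns involving N are ignored), their adenine specificity (TR base is
#' A), the fraction of substituted TR codons that are asparagine codons
#' (AAT/AAC) when a reading frame is known, pairs of identical VRs, and the
#' exact sequence space `4^n` over the `n` variable positions, computed in
#' arbitrary precision (returned as a digit string alongside a numeric
#' approximation).
#'
#' @param vs A [variant_set()].
#' @return An object of class `diversity_report`.
#' @export
diversity_report <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  tr <- strsplit(vs$tr_consensus, "", fixed = TRUE)[[1]]
  vmat <- do.call(rbind, strsplit(unlist(vs$vrs), "", fixed = TRUE))
  differs <- sweep(vmat, 2L, tr, FUN = "!=")
  valid <- sweep(vmat != "N", 2L, tr != "N", FUN = "&")
  var_cols <- which(apply(differs & valid, 2L, any))
  n_var <- length(var_cols)
  adenine_specific <- tr[var_cols] == "A"

  asn_fraction <- NA_real_
  if (!is.null(vs$reading_frame) && n_var > 0L) {
    off <- vs$reading_frame$offset
    tr_codon <- tr
    cols <- var_cols
    if (vs$reading_frame$strand == "-") {
      tr_codon <- strsplit(revcomp(vs$tr_consensus), "", fixed = TRUE)[[1]]
      cols <- length(tr) - var_cols + 1L
    }
    codon_idx <- (cols - 1L - off) %/% 3L
    codon_idx <- unique(codon_idx[codon_idx >= 0L &
                                    off + 3L * (codon_idx + 1L) <= length(tr_codon)])
    if (length(codon_idx)) {
      codons <- vapply(codon_idx, function(ci)
        paste(tr_codon[(off + 3L * ci + 1L):(off + 3L * ci + 3L)],
              collapse = ""), "")
      asn_fraction <- mean(codons %in% c("AAT", "AAC"))
    }
  }

  ids <- names(vs$vrs)
  dup_pairs <- list()
  if (length(ids) > 1L) {
    strs <- unlist(vs$vrs)
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids))
      if (strs[i] == strs[j])
        dup_pairs[[length(dup_pairs) + 1L]] <- c(ids[i], ids[j])
  }

  structure(list(
    dgr_id = vs$dgr_id,
    n_variants = length(vs$vrs),
    variable_positions = var_cols - 1L,        # 0-based
    n_variable_positions = n_var,
    adenine_specific = adenine_specific,
    asn_codon_fraction = asn_fraction,
    identical_vr_pairs = dup_pairs,
    sequence_space = pow4_exact(n_var),
    sequence_space_numeric = 4^n_var),
    class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(paste0("<diversity_report> %s: %d variants, %d variable ",
                     "positions (%d adenine-specific), sequence space %s\n"),
              x$dgr_id, x$n_variants, x$n_variable_positions,
              sum(x$adenine_specific), x$sequence_space))
  invisible(x)
}

#' Exact power of four as a digit string
#'
#' `4^n` exceeds double precision past n = 26, but the sequence-space size
#' must be exact, so it is computed in base-10 bignum arithmetic
#' (repeated multiplication by 4 on a digit vector).
#'
#' @param n Non-negative integer exponent.
#' @return Decimal digit string of `4^n`.
#' @export
pow4_exact <- function(n) {
  stopifnot(n >= 0L)
  digits <- 1L                                  # little-endian base-10 digits
  for (i in seq_len(n)) {
    digits <- digits * 4L
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] + carry
      digits[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

#' Do two aligned genomes differ only inside the VR?
#'
#' Two tropic variants of one phage can be identical along their entire
#' genomes except within the variable repeat. Inputs must be pre-aligned,
#' equal-length strings (whole-genome alignment is out of scope here).
#'
#' @param genome_a,genome_b Equal-length aligned genome strings.
#' @param vr_span 0-based half-open `c(start, end)` interval of the VR.
#' @return `TRUE` iff every differing column lies within `vr_span`
#'   (vacuously `TRUE` with zero differences).
#' @export
genome_pair_vr_only_diff <- function(genome_a, genome_b, vr_span) {
  if (nchar(genome_a) != nchar(genome_b))
    stop("genome_pair_vr_only_diff: genomes must be pre-aligned to equal length")
  a <- strsplit(toupper(genome_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(genome_b), "", fixed = TRUE)[[1]]
  diff <- which(a != b) - 1L
  all(diff >= vr_span[1] & diff < vr_span[2])
}

#' Render a columnar TR/VR alignment with mismatches flagged
#'
#' Text rendering of a variant set: the TR on top, each VR below with `.`
#' at columns identical to the TR and the substituted base at variable
#' columns, plus a marker line flagging adenine-specific columns with `A`
#' and other variable columns with `*`.
#'
#' @param vs A [variant_set()].
#' @return Character vector of lines.
#' @export
render_alignment <- function(vs) {
  tr <- strsplit(vs$tr_consensus, "", fixed = TRUE)[[1]]
  width <- max(nchar(c("TR", names(vs$vrs)))) + 2L
  lines <- sprintf("%-*s%s", width, "TR", vs$tr_consensus)
  rep_cols <- logical(length(tr))
  for (id in names(vs$vrs)) {
    v <- strsplit(vs$vrs[[id]], "", fixed = TRUE)[[1]]
    shown <- ifelse(v == tr, ".", v)
    rep_cols <- rep_cols | (v != tr)
    lines <- c(lines, sprintf("%-*s%s", width, id, paste(shown, collapse = "")))
  }
  marker <- ifelse(rep_cols & tr == "A", "A", ifelse(rep_cols, "*", " "))
  c(lines, sprintf("%-*s%s", width, "", paste(marker, collapse = "")))
}
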