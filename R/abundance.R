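#' Fit a qPCR standard curve
#'
#' Least-squares line Cq = slope * log10(copies) + intercept over a serial
#' dilution of a quantified standard. Amplification efficiency follows from
#' the slope as E = 10^(-1/slope) - 1; a slope of -3.3219 (= -1/log10(2))
#' corresponds to perfect doubling, E = 100%.
#'
#' @param log10_copies log10 copy numbers of the dilution points (>= 3
#'   distinct values).
#' @param cq Measured quantification cycles, same length.
#' @return Object of class `standard_curve`: slope, intercept, r_squared,
#'   efficiency, valid (FALSE when the slope is nonnegative).
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  if (length(log10_copies) < 3 || length(unique(log10_copies)) < 3)
    stop("a standard curve needs at least 3 distinct dilution points")
  if (length(log10_copies) != length(cq))
    stop("log10_copies and cq must have equal length")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  valid <- slope < 0
  if (!valid)
    warning("nonnegative standard-curve slope; curve flagged invalid")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
    valid = valid), class = "standard_curve")
}

#' Absolute quantification: Cq to 16S copies per gram
#'
#' Inverts the standard curve, copies_per_reaction = 10^((cq - intercept) /
#' slope), then converts to copies per gram of input sample with the
#' extraction metadata. Missing Cq (no amplification) is reported as `NA` —
#' below quantification, never zero — so log-scale summaries stay defined.
#'
#' @param cq Quantification cycles (vector; `NA` = undetected).
#' @param curve A valid [fit_standard_curve()] result.
#' @param dilution_factor Template dilution before the reaction (>= 1).
#' @param input_mass_g Sample mass extracted (grams).
#' @param extract_fraction_per_reaction Fraction of the extract loaded per
#'   reaction.
#' @return data.frame with `copies_per_g` and `log10_copies_per_g`.
#' @export
quantify_copies <- function(cq, curve, dilution_factor = 1,
                            input_mass_g = 1,
                            extract_fraction_per_reaction = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("cannot quantify against an invalid standard curve")
  stopifnot(all(dilution_factor >= 1), all(input_mass_g > 0),
            all(extract_fraction_per_reaction > 0),
            all(extract_fraction_per_reaction <= 1))
  per_rxn <- 10^((cq - curve$intercept) / curve$slope)
  copies <- per_rxn * dilution_factor /
    (input_mass_g * extract_fraction_per_reaction)
  data.frame(copies_per_g = copies, log10_copies_per_g = log10(copies))
}

#' Relative abundance of target amplicon features
#'
#' Fraction of each sample's reads falling on the flagged target features
#' (exact-match representatives of the taxon of interest) over all reads in
#' that sample. A sample with zero total reads is reported `NA`, not 0.
#'
#' @param counts Samples-by-features nonnegative count matrix (row names =
#'   sample ids).
#' @param target_features Column names or indices of the target features.
#' @return Named numeric vector of per-sample fractions in \[0, 1\].
#' @export
target_relative_abundance <- function(counts, target_features) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.character(target_features) &&
      !all(target_features %in% colnames(counts)))
    stop("unknown target features")
  totals <- rowSums(counts)
  hit <- if (length(target_features))
    rowSums(counts[, target_features, drop = FALSE]) else
      rep(0, nrow(counts))
  out <- ifelse(totals > 0, hit / totals, NA_real_)
  stats::setNames(out, rownames(counts))
}

#' Length-normalized relative activity of MAGs
#'
#' Per sample, each MAG's mapped read count is normalized to its genome
#' length, and the normalized values are expressed as fractions of the
#' normalized total over all MAGs. Samples with zero mapped reads get `NA`
#' for every MAG.
#'
#' @param counts Samples-by-MAGs nonnegative count matrix.
#' @param lengths_bp Per-MAG total length (bp), positive, one per column.
#' @return Samples-by-MAGs matrix of fractions; rows sum to 1 where defined.
#' @export
mag_relative_activity <- function(counts, lengths_bp) {
  counts <- as.matrix(counts)
  if (length(lengths_bp) != ncol(counts))
    stop("one length per MAG required")
  if (any(lengths_bp <= 0)) stop("MAG lengths must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  norm <- sweep(counts, 2, lengths_bp, "/")
  totals <- rowSums(norm)
  out <- sweep(norm, 1, totals, "/")
  out[totals == 0, ] <- NA_real_
  out
}

#' Fragments per kilobase per million mapped reads
#'
#' fpkm = count * 1e9 / (length_bp * total_mapped). Invariant under joint
#' scaling of counts and totals; linear in counts at fixed totals.
#'
#' @param counts Mapped fragment counts (vector or matrix).
#' @param length_bp Gene length(s), bp, positive.
#' @param total_mapped Per-sample total mapped fragments, positive; `NA` or
#'   zero totals give `NA` FPKM.
#' @return FPKM, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  total_mapped[!is.na(total_mapped) & total_mapped <= 0] <- NA_real_
  counts * 1e9 / (length_bp * total_mapped)
}
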