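#' Fragment-mass model for the alkyl-coenzyme M homolog series
#'
#' Alkyl-CoM thioethers (CnH2n+1-S-C2H4-SO3-) fragment in negative-mode
#' tandem MS into three diagnostic product ions: bisulfite (HSO3-, m/z 80.9),
#' ethenesulfonate (C2H3SO3-, m/z 106.9), and the chain-length-specific
#' alkyl-sulfonate CnH2n+1SO3-. Product-ion m/z values follow a generalized
#' linear mass model with empirical per-atom constants calibrated on authentic
#' hexadecyl- and eicosyl-CoM standards, reported at unit (one-decimal)
#' machine accuracy.
#'
#' @param carbon_mass Effective carbon mass contribution (Da).
#' @param hydrogen_mass Effective hydrogen mass contribution (Da).
#' @param so3_constant Constant term for the SO3 moiety (Da).
#' @param sulfur_mass Monoisotopic sulfur mass (Da), used only for the
#'   precursor (molecular anion) m/z.
#' @param report_decimals Number of decimals the instrument reports.
#' @return An object of class `fragment_mass_model`.
#' @examples
#' m <- fragment_mass_model()
#' fragment_mz(m, "HSO3")      # 80.9
#' fragment_mz(m, "alkyl", 16) # hexadecyl-sulfonate
#' @export
fragment_mass_model <- function(carbon_mass = 12.00055,
                                hydrogen_mass = 1.00837,
                                so3_constant = 79.9,
                                sulfur_mass = 31.97207,
                                report_decimals = 1L) {
  stopifnot(carbon_mass > 0, hydrogen_mass > 0, so3_constant > 0,
            sulfur_mass > 0, report_decimals >= 0)
  structure(
    list(carbon_mass = carbon_mass, hydrogen_mass = hydrogen_mass,
         so3_constant = so3_constant, sulfur_mass = sulfur_mass,
         report_decimals = as.integer(report_decimals)),
    class = "fragment_mass_model")
}

#' Theoretical product-ion m/z for an alkyl-CoM fragment
#'
#' @param model A [fragment_mass_model()].
#' @param fragment One of `"HSO3"`, `"C2H3SO3"`, `"alkyl"`.
#' @param n Alkyl chain length (carbons); required for `fragment = "alkyl"`.
#' @return m/z rounded to the model's reported decimals.
#' @export
fragment_mz <- function(model, fragment = c("HSO3", "C2H3SO3", "alkyl"),
                        n = NULL) {
  stopifnot(inherits(model, "fragment_mass_model"))
  fragment <- match.arg(fragment)
  mz <- switch(fragment,
    HSO3    = model$hydrogen_mass + model$so3_constant,
    C2H3SO3 = 2 * model$carbon_mass + 3 * model$hydrogen_mass +
              model$so3_constant,
    alkyl   = {
      if (is.null(n)) stop("chain length `n` required for alkyl fragments")
      n <- as.integer(n)
      if (any(n < 1L | n > 40L)) stop("alkyl chain length must be in [1, 40]")
      model$carbon_mass * n + model$hydrogen_mass * (2 * n + 1) +
        model$so3_constant
    })
  round(mz, model$report_decimals)
}

#' Precursor m/z of the alkyl-CoM molecular anion
#'
#' The full thioether anion CnH2n+1-S-C2H4-SO3- carries n + 2 carbons,
#' 2n + 5 hydrogens, one sulfur beyond the SO3 moiety, and the SO3 constant.
#'
#' @inheritParams fragment_mz
#' @return m/z rounded to the model's reported decimals.
#' @export
alkylcom_precursor_mz <- function(model, n) {
  stopifnot(inherits(model, "fragment_mass_model"))
  n <- as.integer(n)
  if (any(n < 4L | n > 28L))
    stop("alkyl-CoM chain length must be in [4, 28]")
  mz <- model$carbon_mass * (n + 2) + model$hydrogen_mass * (2 * n + 5) +
    model$sulfur_mass + model$so3_constant
  round(mz, model$report_decimals)
}

#' Build the theoretical MRM transition list for the alkyl-CoM series
#'
#' One precursor (molecular anion) per chain length, paired with each of the
#' three product ions: 3 * (n_max - n_min + 1) transitions.
#'
#' @param model A [fragment_mass_model()].
#' @param n_min,n_max Chain-length range (default the C4-C28 series).
#' @return A data.frame with columns `chain_length`, `precursor_mz`,
#'   `product_mz`, `product_ion` (one of HSO3/C2H3SO3/alkyl).
#' @export
build_transitions <- function(model = fragment_mass_model(),
                              n_min = 4L, n_max = 28L) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min > n_max) stop("n_min must not exceed n_max")
  if (n_min < 4L || n_max > 28L)
    stop("alkyl-CoM series is defined for chain lengths 4..28")
  n <- n_min:n_max
  data.frame(
    chain_length = rep(n, each = 3L),
    precursor_mz = rep(alkylcom_precursor_mz(model, n), each = 3L),
    product_mz   = as.vector(rbind(
      fragment_mz(model, "HSO3"),
      fragment_mz(model, "C2H3SO3"),
      fragment_mz(model, "alkyl", n))),
    product_ion  = rep(c("HSO3", "C2H3SO3", "alkyl"), times = length(n)),
    stringsAsFactors = FALSE)
}

#' Screen an observed MRM run against the theoretical alkyl-CoM transitions
#'
#' A chain length n counts as detected iff some observed transition matches
#' the theoretical precursor(n) -> HSO3- pair within `mz_tolerance` on both
#' m/z axes at intensity strictly greater than `intensity_threshold`.
#' Matches to the other two product ions are recorded as corroboration but
#' are neither necessary nor sufficient for detection.
#'
#' @param observed data.frame with columns `precursor_mz`, `product_mz`,
#'   `intensity` (an observed transition table).
#' @param theoretical Theoretical table from [build_transitions()].
#' @param mz_tolerance Match tolerance (Da) applied to precursor and product.
#' @param intensity_threshold Detection threshold; the qualifying
#'   precursor -> HSO3- intensity must strictly exceed it.
#' @param sample_id Label carried into the result.
#' @return A list with `variety` (an object of class `variety_result`:
#'   `sample_id`, `detected_chain_lengths`, `variety`) and `hits`, a
#'   data.frame of per-chain matches with corroborating ions.
#' @export
screen_alkylcom <- function(observed,
                            theoretical = build_transitions(),
                            mz_tolerance = 0.3,
                            intensity_threshold = 2000,
                            sample_id = NA_character_) {
  stopifnot(mz_tolerance > 0, intensity_threshold >= 0)
  if (is.null(observed) || nrow(observed) == 0L) {
    observed <- data.frame(precursor_mz = numeric(0),
                           product_mz = numeric(0), intensity = numeric(0))
  }
  stopifnot(all(c("precursor_mz", "product_mz", "intensity") %in%
                  names(observed)))

  chains <- unique(theoretical$chain_length)
  hits <- vector("list", length(chains))
  detected <- logical(length(chains))
  for (i in seq_along(chains)) {
    th <- theoretical[theoretical$chain_length == chains[i], ]
    matched_ions <- character(0)
    qual <- NA_real_
    for (j in seq_len(nrow(th))) {
      ok <- abs(observed$precursor_mz - th$precursor_mz[j]) <= mz_tolerance &
            abs(observed$product_mz - th$product_mz[j]) <= mz_tolerance
      if (!any(ok)) next
      best <- max(observed$intensity[ok])
      if (th$product_ion[j] == "HSO3") {
        qual <- best
        if (best > intensity_threshold) {
          detected[i] <- TRUE
          matched_ions <- c(matched_ions, "HSO3")
        }
      } else {
        matched_ions <- c(matched_ions, th$product_ion[j])
      }
    }
    if (detected[i]) {
      hits[[i]] <- data.frame(chain_length = chains[i],
                              qualifying_intensity = qual,
                              matched_ions = paste(matched_ions,
                                                   collapse = ","),
                              stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits))
    hits <- data.frame(chain_length = integer(0),
                       qualifying_intensity = numeric(0),
                       matched_ions = character(0))
  detected_set <- chains[detected]
  variety <- structure(
    list(sample_id = sample_id,
         detected_chain_lengths = detected_set,
         variety = length(detected_set)),
    class = "variety_result")
  list(variety = variety, hits = hits)
}

#' @export
print.variety_result <- function(x, ...) {
  cat("Alkyl-CoM screen:", x$sample_id, "\n")
  cat("  variety:", x$variety, "\n")
  if (x$variety > 0)
    cat("  chain lengths:", paste(sort(x$detected_chain_lengths),
                                  collapse = ", "), "\n")
  invisible(x)
}
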