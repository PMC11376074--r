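#' Classify a sample into the four co-occurrence evidence groups
#'
#' Three boolean markers grade the evidence for in-situ alkylotrophic
#' methanogenesis: presence of Ca. Methanoliparum 16S rRNA genes, acrA
#' transcription, and detection of alkyl-CoM metabolites. Four described
#' combinations define groups 1-4; every other combination is labelled
#' `"other"`:
#' group 1 = (16S, acrA, alkyl-CoM) all present;
#' group 2 = 16S and alkyl-CoM without acrA expression;
#' group 3 = alkyl-CoM only;
#' group 4 = none of the three.
#'
#' @param has_16S,has_acrA_transcript,has_alkylcom Logical vectors
#'   (recycled to common length). `NA` entries refuse classification and
#'   return `NA`.
#' @return Character vector in `{"1","2","3","4","other"}` (or `NA`).
#' @export
classify_evidence <- function(has_16S, has_acrA_transcript, has_alkylcom) {
  n <- max(length(has_16S), length(has_acrA_transcript),
           length(has_alkylcom))
  a <- rep_len(as.logical(has_16S), n)
  b <- rep_len(as.logical(has_acrA_transcript), n)
  c_ <- rep_len(as.logical(has_alkylcom), n)
  out <- rep(NA_character_, n)
  def <- !is.na(a) & !is.na(b) & !is.na(c_)
  out[def &  a &  b &  c_] <- "1"
  out[def &  a & !b &  c_] <- "2"
  out[def & !a & !b &  c_] <- "3"
  out[def & !a & !b & !c_] <- "4"
  out[def & is.na(out)] <- "other"
  if (any(!def))
    warning(sum(!def), " sample(s) with undefined markers not classified")
  out
}

#' Stratified detection proportions
#'
#' For each stratum (degradation degree and, separately, oilfield), the
#' fraction of samples in which the marker was detected, with the totals.
#' Empty strata are simply absent from the output.
#'
#' @param detected Logical vector, one per sample.
#' @param degree Integer degradation degrees 0-4 (NA allowed; excluded).
#' @param oilfield Optional oilfield labels.
#' @return data.frame with columns `stratum_type` ("degree"/"oilfield"),
#'   `stratum`, `n_total`, `n_detected`, `proportion`.
#' @export
detection_summary <- function(detected, degree, oilfield = NULL) {
  stopifnot(length(detected) == length(degree))
  out <- list()
  tab_by <- function(strata, type) {
    keep <- !is.na(strata) & !is.na(detected)
    if (!any(keep)) return(NULL)
    s <- split(detected[keep], strata[keep])
    data.frame(stratum_type = type, stratum = names(s),
               n_total = vapply(s, length, integer(1)),
               n_detected = vapply(s, sum, integer(1)),
               proportion = vapply(s, mean, numeric(1)),
               row.names = NULL)
  }
  out <- rbind(tab_by(degree, "degree"),
               if (!is.null(oilfield)) tab_by(oilfield, "oilfield"))
  out
}

#' Transform expression and degradation degree for regression
#'
#' Covariates are natural-log FPKM, X = ln(FPKM + pseudocount); the
#' response maps the ordinal degree d in 0..4 into a finite logit,
#' Y = logit((d + 0.5) / 5), placing degree 2 at Y = 0 with the five levels
#' symmetric about it. Rows with indeterminate degree are dropped with a
#' message.
#'
#' @param fpkm Matrix or data.frame of per-sample FPKM values (columns =
#'   genes; typically bacterial pooled fumarate-addition genes and archaeal
#'   acrA).
#' @param degrees Integer degrees 0-4 (`NA` = indeterminate).
#' @param pseudocount Positive value added before the log. The default is
#'   small relative to quantifiable expression so the transform stays
#'   log-linear; zeros map to ln(pseudocount).
#' @return Object of class `transformed_xy`: list with `X` (matrix), `Y`
#'   (numeric), `pseudocount`, `n_dropped`.
#' @export
transform_xy <- function(fpkm, degrees, pseudocount = 0.01) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  X <- as.matrix(fpkm)
  if (any(X < 0, na.rm = TRUE)) stop("FPKM values must be nonnegative")
  stopifnot(nrow(X) == length(degrees))
  degrees <- as.integer(degrees)
  if (any(!is.na(degrees) & !(degrees %in% 0:4)))
    stop("degrees must be in {0..4} or NA")
  keep <- !is.na(degrees) & stats::complete.cases(X)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with indeterminate degree or missing FPKM dropped")
  structure(list(
    X = log(X[keep, , drop = FALSE] + pseudocount),
    Y = qlogis((degrees[keep] + 0.5) / 5),
    pseudocount = pseudocount,
    n_dropped = n_dropped), class = "transformed_xy")
}

#' Ridge regression of transformed degradation degree on gene expression
#'
#' Minimizes ||Y - X beta - b||^2 + lambda ||beta||^2. With
#' `fit_intercept = TRUE` (default) the intercept b is estimated and left
#' unpenalized (X and Y are centred, beta solved on the centred problem, b
#' recovered from the means); with `fit_intercept = FALSE` the intercept is
#' fixed at zero. At lambda = 0 the estimate equals ordinary least squares.
#' Solved by augmented least squares via QR: rows sqrt(lambda) I appended
#' to the (centred) design.
#'
#' @param xy A [transform_xy()] result.
#' @param lambda Nonnegative ridge penalty.
#' @param fit_intercept Estimate an unpenalized intercept?
#' @return Object of class `ridge_fit`: `beta` (named), `intercept`,
#'   `lambda`, `fitted`, `residuals`.
#' @export
fit_ridge <- function(xy, lambda = 0, fit_intercept = TRUE) {
  stopifnot(inherits(xy, "transformed_xy"))
  if (lambda < 0) stop("lambda must be nonnegative")
  X <- xy$X; Y <- xy$Y
  p <- ncol(X); n <- nrow(X)
  if (lambda == 0 && n < p + as.integer(fit_intercept) + 1)
    stop("too few rows for an unpenalized fit; increase lambda")
  if (fit_intercept) {
    xm <- colMeans(X); ym <- mean(Y)
    Xc <- sweep(X, 2, xm); Yc <- Y - ym
  } else {
    Xc <- X; Yc <- Y
  }
  aug_X <- rbind(Xc, diag(sqrt(lambda), p))
  aug_Y <- c(Yc, rep(0, p))
  qrx <- qr(aug_X)
  if (qrx$rank < p)
    stop("design is rank-deficient at lambda = 0; use lambda > 0")
  beta <- drop(qr.coef(qrx, aug_Y))
  names(beta) <- colnames(X)
  intercept <- if (fit_intercept) ym - sum(xm * beta) else 0
  fitted <- drop(X %*% beta) + intercept
  structure(list(beta = beta, intercept = intercept, lambda = lambda,
                 fit_intercept = fit_intercept,
                 fitted = fitted, residuals = Y - fitted,
                 n = n), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge fit (lambda = %g, n = %d)\n", x$lambda, x$n))
  eq <- paste(sprintf("%.3f*%s", x$beta, names(x$beta)), collapse = " + ")
  cat("  Y =", eq,
      if (x$fit_intercept) sprintf("+ %.3f", x$intercept) else "", "\n")
  invisible(x)
}

#' Select the ridge penalty by leave-one-out cross-validation
#'
#' Exact LOO: each sample is held out in turn and predicted from a fit on
#' the rest; lambda minimizing the mean squared prediction error over a
#' log-spaced grid wins.
#'
#' @param xy A [transform_xy()] result.
#' @param lambda_grid Candidate penalties; default 25 log-spaced values in
#'   \[1e-4, 1e3\] plus 0.
#' @param fit_intercept Passed to [fit_ridge()].
#' @return List: `lambda` (selected), `cv_mse` (named by grid value).
#' @export
select_lambda_loocv <- function(xy,
                                lambda_grid = c(0, 10^seq(-4, 3,
                                                          length.out = 25)),
                                fit_intercept = TRUE) {
  stopifnot(inherits(xy, "transformed_xy"))
  n <- nrow(xy$X)
  mse <- vapply(lambda_grid, function(lam) {
    err <- vapply(seq_len(n), function(i) {
      sub <- structure(list(X = xy$X[-i, , drop = FALSE], Y = xy$Y[-i],
                            pseudocount = xy$pseudocount, n_dropped = 0L),
                       class = "transformed_xy")
      fit <- fit_ridge(sub, lambda = lam, fit_intercept = fit_intercept)
      pred <- sum(xy$X[i, ] * fit$beta) + fit$intercept
      (xy$Y[i] - pred)^2
    }, numeric(1))
    mean(err)
  }, numeric(1))
  names(mse) <- signif(lambda_grid, 4)
  list(lambda = lambda_grid[which.min(mse)], cv_mse = mse)
}
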