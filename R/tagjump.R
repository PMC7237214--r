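#' Fit the tag-jump contamination model
#'
#' Tag jumping (index hopping) leaks a small fraction of an abundant OTU's
#' reads into other multiplexed samples. Its footprint is measured in the
#' negative controls: for every OTU with a nonzero count in any control,
#' pairs are formed of `x` = the OTU's maximum count over all non-control
#' samples and `y` = its count in each control, and a through-origin
#' quantile regression `y ~ beta * x` is fitted at level `tau` by direct
#' minimization of the check loss `sum(rho_tau(y - beta * x))`.
#'
#' The fit is through the origin because an OTU absent from the sequencing
#' run cannot contaminate anything, so zero maximum abundance must imply
#' zero expected subtraction. The check loss in `beta` is piecewise linear
#' and convex with kinks at the observed slopes `y/x`, so the minimizer is
#' found exactly by evaluating the loss at every kink (ties resolved to
#' the smallest minimizing slope).
#'
#' @param x a [RarescapeExperiment-class], or a count matrix (OTUs x
#'   samples).
#' @param controls control sample ids; defaults to `controlSamples(x)`.
#' @param tau quantile level in (0, 1); default 0.90.
#' @return a [TagJumpModel-class]. If the controls contain no reads at
#'   all, `beta = 0`.
#' @export
fitTagJump <- function(x, controls = NULL, tau = 0.90) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly in (0, 1)")
  cnt <- if (is(x, "RarescapeExperiment")) otuCounts(x) else as.matrix(x)
  if (is.null(controls) && is(x, "RarescapeExperiment")) {
    controls <- controlSamples(x)
  }
  controls <- as.character(controls)
  if (!length(controls)) stop("at least one control sample is required")
  miss <- setdiff(controls, colnames(cnt))
  if (length(miss)) stop("control(s) not in table: ",
                         paste(miss, collapse = ", "))
  real <- setdiff(colnames(cnt), controls)
  ctl <- cnt[, controls, drop = FALSE]
  hit <- rowSums(ctl) > 0
  if (!any(hit)) {
    return(new("TagJumpModel", beta = 0, tau = tau, nPoints = 0L))
  }
  M <- apply(cnt[hit, real, drop = FALSE], 1L, max)
  xs <- rep(M, times = length(controls))
  ys <- as.vector(ctl[hit, , drop = FALSE])
  keep <- xs > 0
  xs <- xs[keep]; ys <- ys[keep]
  if (!length(xs)) {
    return(new("TagJumpModel", beta = 0, tau = tau, nPoints = 0L))
  }
  beta <- .qrOriginFit(xs, ys, tau)
  new("TagJumpModel", beta = beta, tau = tau, nPoints = length(xs))
}

# exact through-origin quantile regression: evaluate the check loss at
# every candidate slope y/x (plus 0) and take the smallest minimizer
.qrOriginFit <- function(xs, ys, tau) {
  cand <- sort(unique(c(0, ys / xs)))
  loss <- vapply(cand, function(b) {
    r <- ys - b * xs
    sum(r * (tau - (r < 0)))
  }, numeric(1))
  cand[which.min(loss)]  # which.min takes the first, i.e. smallest slope
}

#' Subtract modelled tag-jump reads
#'
#' Applies a fitted [TagJumpModel-class]: for OTU i in sample j, the
#' corrected count is `max(0, count - ceiling(beta * M))` where `M` is the
#' maximum count of OTU i over all samples *other than* j. Using the
#' out-of-sample maximum means a sample's own dominant OTU is not
#' penalized by its own abundance; the ceiling makes the subtraction
#' conservative (at least one read is removed wherever contamination is
#' possible at all). Counts stay integral and non-negative, and applying
#' the correction twice can never increase a count.
#'
#' @param x a [RarescapeExperiment-class] or count matrix.
#' @param model a [TagJumpModel-class] from [fitTagJump()].
#' @return object of the same type as `x` with corrected counts.
#' @export
applyTagJump <- function(x, model) {
  stopifnot(is(model, "TagJumpModel"))
  cnt <- if (is(x, "RarescapeExperiment")) otuCounts(x) else as.matrix(x)
  beta <- model@beta
  if (beta > 0 && nrow(cnt) > 0L && ncol(cnt) > 1L) {
    ord <- t(apply(cnt, 1L, function(v) -sort(-v, partial = 1:2)[1:2]))
    mx <- ord[, 1L]; mx2 <- ord[, 2L]
    nmax <- rowSums(cnt == mx)
    for (j in seq_len(ncol(cnt))) {
      Mj <- ifelse(cnt[, j] == mx & nmax == 1L, mx2, mx)
      cnt[, j] <- pmax(0L, cnt[, j] - as.integer(ceiling(beta * Mj)))
    }
  }
  if (is(x, "RarescapeExperiment")) {
    SummarizedExperiment::assay(x, "counts") <- cnt
    validObject(x)
    x
  } else {
    cnt
  }
}

#' One-step decontamination
#'
#' Convenience wrapper: fit the tag-jump model on the controls and apply
#' the subtraction to the whole table.
#'
#' @inheritParams fitTagJump
#' @return list with elements `x` (corrected object) and `model`.
#' @export
decontaminate <- function(x, controls = NULL, tau = 0.90) {
  model <- fitTagJump(x, controls = controls, tau = tau)
  list(x = applyTagJump(x, model), model = model)
}
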