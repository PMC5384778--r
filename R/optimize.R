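#' Central finite-difference gradient
#'
#' Generic gradient of a scalar objective by central differences with step
#' `h` per parameter. An optional `free` mask marks parameters to be held
#' fixed; their gradient entries are exactly 0 and the objective is never
#' evaluated at perturbations of them. (For FFD coefficients the registration
#' engine uses a specialized path that updates only the joint-histogram
#' contributions of the voxels inside each control point's support; the two
#' agree to full recomputation.)
#'
#' @param objective function of a numeric parameter vector returning a scalar.
#' @param params numeric parameter vector.
#' @param h positive step (scalar or per-parameter).
#' @param free optional logical vector; FALSE entries are frozen.
#' @return numeric gradient vector.
#' @export
finite_diff_gradient <- function(objective, params, h = 1e-3, free = NULL) {
  h <- rep_len(as.numeric(h), length(params))
  if (any(h <= 0)) stop("finite-difference step h must be positive")
  if (is.null(free)) free <- rep(TRUE, length(params))
  g <- numeric(length(params))
  for (i in seq_along(params)) {
    if (!free[i]) next
    up <- params; up[i] <- up[i] + h[i]
    dn <- params; dn[i] <- dn[i] - h[i]
    fu <- objective(up); fd <- objective(dn)
    if (!is.finite(fu) || !is.finite(fd))
      stop("objective not finite at perturbation of parameter ", i)
    g[i] <- (fu - fd) / (2 * h[i])
  }
  g
}

#' Gradient ascent with step halving
#'
#' Maximizes `objective` starting from `params0`. Each iteration computes a
#' gradient (via `gradient_fn`, by default central finite differences), steps
#' along the max-norm-normalized direction by the current step length, and
#' accepts only strict improvements; a rejected step halves the step length.
#' Terminates when the step falls below `min_step`, the improvement falls
#' below `tol`, or `max_iter` is reached. The procedure contains no
#' randomness: identical inputs give identical trajectories.
#'
#' @param objective scalar function to maximize.
#' @param params0 initial parameter vector.
#' @param config list with entries `max_iter`, `initial_step` (in parameter
#'   units, e.g. mm), `step_shrink`, `min_step`, `tol`, `h` (finite-difference
#'   step), `free` (optional logical mask).
#' @param gradient_fn optional `function(params)` returning the gradient;
#'   defaults to [finite_diff_gradient()] on `objective`.
#' @return list with `params` (the maximizer found) and `state`, an
#'   `optimizer_state` holding `iteration`, `objective`, `step_length`,
#'   `gradient_norm`, `converged`, `accepted_step_sum` and the accepted-step
#'   `history` of (iteration, objective) pairs.
#' @export
gradient_ascent <- function(objective, params0, config = list(),
                            gradient_fn = NULL) {
  cfg <- utils::modifyList(list(max_iter = 100L, initial_step = 1,
                                step_shrink = 0.5, min_step = 1e-3,
                                tol = 1e-5, h = 0.5, free = NULL), config)
  if (cfg$max_iter < 0 || cfg$initial_step <= 0 || cfg$min_step <= 0 ||
      cfg$step_shrink <= 0 || cfg$step_shrink >= 1)
    stop("optimizer config values must be positive (and step_shrink in (0,1))")
  if (is.null(gradient_fn))
    gradient_fn <- function(p) finite_diff_gradient(objective, p, cfg$h, cfg$free)
  params <- as.numeric(params0)
  f <- objective(params)
  if (!is.finite(f)) stop("objective not finite at the initial parameters")
  step <- cfg$initial_step
  history <- list(c(0, f))
  accepted <- 0L; it <- 0L; converged <- FALSE; gnorm <- NA_real_
  step_sum <- 0
  while (it < cfg$max_iter && step >= cfg$min_step) {
    it <- it + 1L
    g <- gradient_fn(params)
    gnorm <- max(abs(g))
    if (!is.finite(gnorm) || gnorm == 0) { converged <- TRUE; break }
    dir <- g / gnorm
    gain_total <- 0
    moves <- 0L
    # a computed gradient direction is reused while it keeps paying off
    # (up to a fixed number of moves), then a fresh gradient is taken
    while (step >= cfg$min_step && moves < 10L) {
      cand <- params + step * dir
      fc <- objective(cand)
      if (is.finite(fc) && fc > f) {
        gain_total <- gain_total + (fc - f)
        f <- fc; params <- cand
        step_sum <- step_sum + step
        accepted <- accepted + 1L
        moves <- moves + 1L
        history[[length(history) + 1L]] <- c(it, f)
        next
      }
      if (moves > 0L) break  # direction exhausted; recompute gradient
      step <- step * cfg$step_shrink
    }
    if (moves == 0L || gain_total < cfg$tol) { converged <- TRUE; break }
  }
  if (step < cfg$min_step) converged <- TRUE
  hist <- do.call(rbind, history)
  colnames(hist) <- c("iteration", "objective")
  state <- structure(list(iteration = it, objective = f, step_length = step,
                          gradient_norm = gnorm, converged = converged,
                          accepted_steps = accepted,
                          accepted_step_sum = step_sum, history = hist),
                     class = "optimizer_state")
  list(params = params, state = state)
}

#' Steepest ascent with golden-section line search
#'
#' Like [gradient_ascent()] but each iteration maximizes the objective along
#' the gradient direction by golden-section search over `[0, initial_step]`.
#'
#' @inheritParams gradient_ascent
#' @export
steepest_ascent <- function(objective, params0, config = list(),
                            gradient_fn = NULL) {
  cfg <- utils::modifyList(list(max_iter = 100L, initial_step = 1,
                                min_step = 1e-3, tol = 1e-5, h = 0.5,
                                free = NULL), config)
  if (is.null(gradient_fn))
    gradient_fn <- function(p) finite_diff_gradient(objective, p, cfg$h, cfg$free)
  params <- as.numeric(params0)
  f <- objective(params)
  if (!is.finite(f)) stop("objective not finite at the initial parameters")
  history <- list(c(0, f))
  it <- 0L; converged <- FALSE; gnorm <- NA_real_; step_sum <- 0; accepted <- 0L
  gr <- (sqrt(5) - 1) / 2
  while (it < cfg$max_iter) {
    it <- it + 1L
    g <- gradient_fn(params)
    gnorm <- max(abs(g))
    if (!is.finite(gnorm) || gnorm == 0) { converged <- TRUE; break }
    dir <- g / gnorm
    f1d <- function(s) objective(params + s * dir)
    lo <- 0; hi <- cfg$initial_step
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- f1d(x1); f2 <- f1d(x2)
    while (hi - lo > cfg$min_step) {
      if (f1 < f2) { lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- f1d(x2) }
      else { hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- f1d(x1) }
    }
    sbest <- (lo + hi) / 2
    fc <- f1d(sbest)
    if (!is.finite(fc) || fc <= f) { converged <- TRUE; break }
    params <- params + sbest * dir
    step_sum <- step_sum + sbest
    accepted <- accepted + 1L
    gain <- fc - f; f <- fc
    history[[length(history) + 1L]] <- c(it, f)
    if (gain < cfg$tol) { converged <- TRUE; break }
  }
  hist <- do.call(rbind, history)
  colnames(hist) <- c("iteration", "objective")
  state <- structure(list(iteration = it, objective = f,
                          step_length = cfg$initial_step,
                          gradient_norm = gnorm, converged = converged,
                          accepted_steps = accepted,
                          accepted_step_sum = step_sum, history = hist),
                     class = "optimizer_state")
  list(params = params, state = state)
}
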