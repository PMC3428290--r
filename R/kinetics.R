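# Fraction of native inter-strand contacts (Qb) over time and the
# single-exponential decay fit A*exp(-t/tau) + B that summarises how fast
# the duplex loses its native pairing.

#' Native inter-strand contacts of a reference structure
#'
#' All heavy-atom pairs between the two RNA strands closer than `cutoff`
#' in the reference frame, with their reference distances. These define
#' Qb = fraction of such pairs still intact at a later time.
#'
#' @param ref an `md_traj` (its `frame`-th frame is the reference).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param frame reference frame index (default 1).
#' @param chains length-2 character vector naming the two strands;
#'   defaults to the RNA chains.
#' @return data.frame of class `native_contacts` with columns `i`, `j`
#'   (atom indices into the topology) and `ref_dist_A`; zero rows (with a
#'   warning) when the strands are not in contact.
#' @export
native_contacts <- function(ref, cutoff = 4.5, frame = 1, chains = NULL) {
  topo <- ref$atoms
  cc <- chain_class(topo)
  if (is.null(chains)) chains <- names(cc)[cc == "rna"]
  if (length(chains) != 2) {
    stop("native contacts need exactly two strand chains (got ",
      length(chains), ")")
  }
  heavy <- topo$element != "H"
  i1 <- which(topo$chain == chains[1] & heavy)
  i2 <- which(topo$chain == chains[2] & heavy)
  xyz <- frame_coords(ref, frame)
  d2 <- outer(rowSums(xyz[i1, , drop = FALSE]^2),
    rowSums(xyz[i2, , drop = FALSE]^2), `+`
  ) - 2 * xyz[i1, , drop = FALSE] %*% t(xyz[i2, , drop = FALSE])
  d <- sqrt(pmax(d2, 0))
  hit <- which(d < cutoff, arr.ind = TRUE)
  out <- data.frame(
    i = i1[hit[, 1]], j = i2[hit[, 2]],
    ref_dist_A = d[hit]
  )
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no native inter-strand contacts within ", cutoff, " A")
  }
  class(out) <- c("native_contacts", "data.frame")
  out
}

#' Fraction of native contacts per frame (Qb series)
#'
#' A native pair is retained in a frame when its distance does not exceed
#' `tolerance_factor` times its reference distance; Qb is the retained
#' fraction, 1 on the reference frame by construction and invariant under
#' rigid motion of a frame.
#'
#' @param traj an `md_traj`.
#' @param native a [native_contacts()] table (non-empty).
#' @param tolerance_factor retention tolerance relative to the reference
#'   distance (default 1.2).
#' @return data.frame of class `qb_series` with columns `time_ps`, `qb`.
#' @export
qb_series <- function(traj, native, tolerance_factor = 1.2) {
  if (nrow(native) == 0) stop("empty native contact list")
  lim <- native$ref_dist_A * tolerance_factor
  qb <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$xyz[, , f]
    d <- sqrt(rowSums((xyz[native$i, , drop = FALSE] -
      xyz[native$j, , drop = FALSE])^2))
    mean(d <= lim)
  }, numeric(1))
  structure(
    data.frame(time_ps = frame_times(traj), qb = qb),
    class = c("qb_series", "data.frame")
  )
}

#' Single-exponential decay fit A*exp(-t/tau) + B
#'
#' Least-squares fit of the three-parameter exponential to a time series,
#' e.g. a Qb decay or a saturating base-pair distance ramp (negative
#' amplitude). Initialisation: `B0` = mean of the last 10% of `y`,
#' `A0 = y(0) - B0`, `tau0` = the first time at which `|y - B0|` falls
#' below `|A0|/e` (falling back to a third of the time range), followed by
#' Levenberg-Marquardt refinement with tau constrained positive.
#'
#' @param x times, or a `qb_series` / data.frame whose `time_ps` column is
#'   converted to ns (a plain numeric vector is taken to be in ns
#'   already).
#' @param y values in `[0, 1]`-ish scale (ignored when `x` is a table).
#' @return list of class `exp_fit`: `A`, `tau` (time units of the fit,
#'   ns for Qb input), `B`, `t_half` (= tau * ln 2), `rss`, `converged`,
#'   `n`.
#' @export
fit_exponential <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if ("time_ps" %in% names(x)) {
      tt <- x$time_ps / 1000
      yy <- if ("qb" %in% names(x)) x$qb else x$value
    } else {
      tt <- x[[1]]
      yy <- x[[2]]
    }
  } else {
    tt <- as.numeric(x)
    yy <- as.numeric(y)
  }
  if (length(tt) < 4) stop("exponential fit needs at least 4 points")
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing")
  if (stats::sd(yy) == 0) stop("degenerate fit: y is constant")

  n <- length(yy)
  b0 <- mean(yy[max(1, ceiling(0.9 * n)):n])
  a0 <- yy[1] - b0
  tau0 <- NA_real_
  if (a0 != 0) {
    below <- which(abs(yy - b0) < abs(a0) / exp(1))
    if (length(below) > 0) tau0 <- tt[below[1]] - tt[1]
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
  if (a0 == 0) a0 <- diff(range(yy))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A * exp(-tt / tau) + B,
      start = list(A = a0, tau = tau0, B = b0),
      lower = c(A = -Inf, tau = 1e-12, B = -Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(
        A = a0, tau = tau0, B = b0, t_half = tau0 * log(2),
        rss = sum((yy - (a0 * exp(-tt / tau0) + b0))^2),
        converged = FALSE, n = n
      ),
      class = "exp_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(
      A = unname(cf["A"]), tau = unname(cf["tau"]), B = unname(cf["B"]),
      t_half = unname(cf["tau"]) * log(2),
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv, n = n
    ),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(
    "<exp_fit> y = A*exp(-t/tau) + B\n",
    sprintf(
      "  A = %.6g, tau = %.6g, B = %.6g (t_half = %.6g)\n",
      x$A, x$tau, x$B, x$t_half
    ),
    sprintf(
      "  rss = %.3g over %d points; converged: %s\n", x$rss, x$n,
      x$converged
    ),
    sep = ""
  )
  invisible(x)
}
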