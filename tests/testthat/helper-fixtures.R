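## Shared fixtures and independent oracles for the test suite.

typ <- function() typical_subject()

## Hand-rolled order-statistic quantile: rank (N+1)p with linear
## interpolation, clamped to the sample range. Independent of
## stats::quantile; the oracle for prediction_interval().
rank_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  r <- (n + 1) * p
  if (r <= 1) return(xs[1])
  if (r >= n) return(xs[n])
  lo <- floor(r)
  xs[lo] + (r - lo) * (xs[lo + 1] - xs[lo])
}

## Reference ODE solution via deSolve (lsoda) on the plain-R right-hand
## side pk_rhs(); fully independent of the compiled integrator.
desolve_profile <- function(params, subject, regimen, times,
                            eta_iiv = rifmipd:::zero_iiv(),
                            iov_etas = NULL) {
  iov <- rifmipd:::as_iov_matrix(iov_etas)
  s <- as.list(subject)
  ip <- rifmipd:::individual_params(params, s$ffm, eta_iiv)
  eta_of_day <- function(day) {
    key <- as.character(day)
    if (!is.null(iov) && key %in% rownames(iov)) iov[key, ]
    else rifmipd:::zero_iov()
  }
  no_dose <- regimen[0, , drop = FALSE]
  rhs <- function(t, y, parms) {
    names(y) <- c("depot", "central", "enz", "cum_auc", "cum_elim")
    e_now <- eta_of_day(floor(t / 24) + 1)
    d <- pk_rhs(y, t, params, subject, eta_iiv, e_now, no_dose)
    past <- regimen[regimen$time < t & regimen$amt > 0, , drop = FALSE]
    if (nrow(past)) {
      for (j in seq_len(nrow(past))) {
        e_d <- eta_of_day(floor(past$time[j] / 24) + 1)
        mtt <- ip$mtt * exp(e_d[["mtt"]])
        f <- bioavailability(past$amt[j], params, e_d[["f"]])
        d[["depot"]] <- d[["depot"]] +
          transit_input_rate(t - past$time[j], past$amt[j], f, mtt, ip$nn)
      }
    }
    list(unname(d))
  }
  tt <- sort(unique(c(0, regimen$time, times)))
  out <- deSolve::lsoda(c(0, 0, 1, 0, 0), times = tt, func = rhs,
                        parms = NULL, rtol = 1e-9, atol = 1e-11, hmax = 0.25)
  res <- out[match(times, tt), -1, drop = FALSE]
  colnames(res) <- c("depot", "central", "enz", "cum_auc", "cum_elim")
  res
}
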