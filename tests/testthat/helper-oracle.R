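# Independent numerical oracle: adaptive ODE integration of the compartmental
# infusion system (deSolve::lsoda), integrated segment-wise between infusion
# on/off breakpoints so the piecewise-constant input is handled exactly.
ode_conc <- function(params, doses, times) {
  p <- as.list(params)
  two_cmt <- !is.null(p$Q) && !is.na(p$Q) && p$Q > 0 &&
    !is.null(p$V2) && !is.na(p$V2) && p$V2 > 0
  k10 <- p$CL / p$V1
  k12 <- if (two_cmt) p$Q / p$V1 else 0
  k21 <- if (two_cmt) p$Q / p$V2 else 0
  rate_at <- function(t) {
    sum(ifelse(t >= doses$start & t < doses$start + doses$duration,
               doses$amount / doses$duration, 0))
  }
  deriv <- function(t, y, parms) {
    r <- parms$rate
    list(c(r - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  breaks <- sort(unique(c(0, doses$start, doses$start + doses$duration, times)))
  breaks <- breaks[breaks >= 0]
  y <- c(0, 0)
  out <- setNames(numeric(length(times)), NULL)
  if (any(times <= 0)) out[times <= 0] <- 0
  for (i in seq_len(length(breaks) - 1)) {
    seg <- c(breaks[i], breaks[i + 1])
    r <- rate_at(mean(seg))
    sol <- deSolve::lsoda(y, seg, deriv, parms = list(rate = r),
                          rtol = 1e-11, atol = 1e-11)
    y <- as.numeric(sol[nrow(sol), 2:3])
    hit <- which(abs(times - seg[2]) < 1e-12)
    if (length(hit)) out[hit] <- y[1] / p$V1
  }
  out
}

# random structural parameters / regimens for oracle comparisons
random_pk_case <- function(two_cmt = FALSE) {
  params <- list(CL = runif(1, 0.05, 8), V1 = runif(1, 0.5, 50),
                 Q = NA_real_, V2 = NA_real_)
  if (two_cmt) {
    params$Q <- runif(1, 0.1, 6)
    params$V2 <- runif(1, 0.5, 60)
  }
  tinf <- runif(1, 0.25, 2)
  tau <- tinf + runif(1, 2, 16)
  list(params = params, dose = runif(1, 5, 1500), tau = tau, tinf = tinf)
}
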