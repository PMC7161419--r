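# Internal helpers shared across modules.

#' Signal a classed error
#'
#' All user-facing errors in the package carry a condition class of the form
#' `reachkin_<kind>_error` so callers can handle specific failure modes.
#'
#' @noRd
rk_abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("reachkin_", class, "_error"), "reachkin_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rk_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("reachkin_", class, "_warning"), "reachkin_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-unit seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Smoothstep ramp 3u^2 - 2u^3 on [0, 1] and its running integral.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}
smoothstep_int <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 - u^4 / 2
}

# Unit-peak asymmetric bump on [0, 1]: g(u) = (u/m)^p ((1-u)/(1-m))^q with
# p = m * kappa, q = (1 - m) * kappa, so the mode sits at m and g(m) = 1.
# kappa > 0 controls how peaked the bump is (kappa -> 0 flattens it).
beta_bump <- function(u, m, kappa) {
  p <- m * kappa
  q <- (1 - m) * kappa
  out <- numeric(length(u))
  ok <- u > 0 & u < 1
  out[ok] <- exp(p * (log(u[ok]) - log(m)) +
                 q * (log1p(-u[ok]) - log1p(-m)))
  out
}

# Running integral of beta_bump from 0 to u (closed form via pbeta).
beta_bump_int <- function(u, m, kappa) {
  p <- m * kappa
  q <- (1 - m) * kappa
  cst <- exp(lbeta(p + 1, q + 1) - p * log(m) - q * log1p(-m))
  u <- pmin(pmax(u, 0), 1)
  cst * stats::pbeta(u, p + 1, q + 1)
}

# Running integral of w * g(w) from 0 to u.
beta_bump_int_t <- function(u, m, kappa) {
  p <- m * kappa
  q <- (1 - m) * kappa
  cst <- exp(lbeta(p + 2, q + 1) - p * log(m) - q * log1p(-m))
  u <- pmin(pmax(u, 0), 1)
  cst * stats::pbeta(u, p + 2, q + 1)
}

# Cumulative trapezoidal integral of y over x.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The eleven kinematic parameter names in canonical report order.
PARAM_NAMES <- c("MT", "MWV", "MWDec", "MTD", "MGA", "MGCV",
                 "TMWV", "TMWDec", "TMTD", "TMGA", "TMGCV")
CONDITIONS <- c("A", "B", "C", "D", "E")
GROUPS <- c("TC", "Control")
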