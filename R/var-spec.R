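#' Specify a vector-autoregressive generative process
#'
#' A `var_spec` describes a stationary VAR(p) process
#' \deqn{x_t = \sum_{k=1}^{p} A_k x_{t-k} + \epsilon_t,\qquad
#'       \epsilon_t \sim N(0, \Sigma),}
#' where entry `coeffs[[k]][i, j]` is the influence of channel `j` at lag `k`
#' on channel `i`. It is the generative twin of the model fitted by
#' [fit_mvar()] and the carrier of planted ground-truth connectivity in
#' simulation scenarios.
#'
#' @param coeffs list of `p` square numeric coefficient matrices
#'   `A(1) ... A(p)`.
#' @param noise_cov symmetric positive-definite innovation covariance;
#'   defaults to the identity.
#' @param labels character vector of channel (region) names.
#'
#' @return An object of class `var_spec` with fields `n_channels`, `order`,
#'   `coeffs`, `noise_cov`, `labels`.
#' @seealso [simulate_var()], [hub_var_spec()], [companion_matrix()]
#' @export
var_spec <- function(coeffs, noise_cov = NULL, labels = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  stopifnot(is.list(coeffs), length(coeffs) >= 1L)
  n <- nrow(coeffs[[1L]])
  for (A in coeffs) {
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n) {
      stop("all coefficient matrices must be square with matching dimension")
    }
  }
  if (is.null(noise_cov)) noise_cov <- diag(n)
  if (!is.matrix(noise_cov) || any(dim(noise_cov) != n)) {
    stop("noise_cov must be ", n, " x ", n)
  }
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8) {
    stop("noise_cov must be symmetric")
  }
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("noise_cov must be positive definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  structure(
    list(n_channels = n, order = length(coeffs), coeffs = coeffs,
         noise_cov = noise_cov, labels = as.character(labels)),
    class = "var_spec"
  )
}

#' Companion matrix and spectral radius of a VAR specification
#'
#' The VAR(p) process is stationary iff the spectral radius of its
#' `np x np` companion matrix is below 1.
#'
#' @param spec a [var_spec()] or fitted [fit_mvar()] model.
#' @return `companion_matrix()` returns the companion matrix;
#'   `spectral_radius()` its largest absolute eigenvalue.
#' @export
companion_matrix <- function(spec) {
  n <- spec$n_channels %||% nrow(spec$coeffs[[1L]])
  p <- spec$order
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, (k - 1L) * n + 1:n] <- spec$coeffs[[k]]
  if (p > 1L) {
    C[(n + 1L):(n * p), 1:(n * (p - 1L))] <- diag(n * (p - 1L))
  }
  C
}

#' @rdname companion_matrix
#' @export
spectral_radius <- function(spec) {
  max(Mod(eigen(companion_matrix(spec), only.values = TRUE)$values))
}

#' @export
print.var_spec <- function(x, ...) {
  cat("VAR(", x$order, ") specification: ", x$n_channels, " channels [",
      paste(x$labels, collapse = ", "), "]\n", sep = "")
  cat("  spectral radius:", format(spectral_radius(x), digits = 4), "\n")
  invisible(x)
}

#' Shipped six-region hub connectivity templates
#'
#' Directed-coupling templates over the six regions ACC, MCC, lSMC, rSMC,
#' PCC, ESC used throughout the simulation scenarios:
#'
#' * `"PCC-hub"`: PCC sends to MCC, lSMC, rSMC and ESC; ACC sends to PCC and
#'   lSMC; MCC and PCC are bidirectionally coupled, as are MCC and ESC. The
#'   posterior-cingulate (default-mode) node is the dominant out-degree hub.
#' * `"MCC-hub"`: MCC is bidirectionally coupled with all five other
#'   regions; the midcingulate (attention-network) node is the hub.
#' * `"null"`: no cross-channel coupling; six independent AR(2) channels.
#'
#' Every template is a VAR(2): each channel carries self-dynamics
#' `self_lag1` at lag 1 and `self_lag2` at lag 2 (a damped second-order
#' recursion so that model-order selection has a genuine order-2 truth to
#' find), and every directed edge contributes `coupling` at lag 1. The
#' default weights keep the companion spectral radius comfortably below 1
#' for all three templates.
#'
#' @param template one of `"PCC-hub"`, `"MCC-hub"`, `"null"`.
#' @param coupling lag-1 weight of each planted directed edge.
#' @param self_lag1,self_lag2 diagonal self-coupling at lags 1 and 2.
#' @param noise_sd innovation standard deviation (covariance is
#'   `noise_sd^2 * I`).
#' @return A [var_spec()] with attribute `"adjacency"`: the planted boolean
#'   edge matrix with `[i, j] = TRUE` meaning channel `j` drives channel `i`.
#' @export
hub_var_spec <- function(template = c("PCC-hub", "MCC-hub", "null"),
                         coupling = 0.3, self_lag1 = 0.4, self_lag2 = -0.25,
                         noise_sd = 1) {
  template <- match.arg(template)
  labels <- c("ACC", "MCC", "lSMC", "rSMC", "PCC", "ESC")
  n <- length(labels)
  edges <- switch(template,
    "PCC-hub" = rbind(
      c("PCC", "MCC"), c("PCC", "lSMC"), c("PCC", "rSMC"), c("PCC", "ESC"),
      c("ACC", "PCC"), c("ACC", "lSMC"),
      c("MCC", "PCC"), c("MCC", "ESC"), c("ESC", "MCC")
    ),
    "MCC-hub" = {
      others <- setdiff(labels, "MCC")
      rbind(cbind("MCC", others), cbind(others, "MCC"))
    },
    "null" = NULL
  )
  A1 <- diag(self_lag1, n)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      j <- match(edges[r, 1L], labels)   # source
      i <- match(edges[r, 2L], labels)   # target
      A1[i, j] <- A1[i, j] + coupling
      adj[i, j] <- TRUE
    }
  }
  A2 <- diag(self_lag2, n)
  spec <- var_spec(list(A1, A2), noise_cov = diag(noise_sd^2, n),
                   labels = labels)
  sr <- spectral_radius(spec)
  if (sr >= 1) {
    stop("template '", template, "' with these weights is non-stationary ",
         "(spectral radius ", format(sr, digits = 4), ")")
  }
  attr(spec, "adjacency") <- adj
  attr(spec, "template") <- template
  spec
}
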