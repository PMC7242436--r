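#' Write a fitted model to disk
#'
#' Serializes the posterior-mean estimates and hyperparameters as JSON at
#' full double precision; [read_model()] round-trips to within 1e-12
#' relative error.  The stochasticity invariants are checked before
#' writing (each `theta` row, `phi` column and `eta` row must sum to 1;
#' `psi` must lie strictly in (0, 1)).
#'
#' @param estimates a `mixehr_estimates`.
#' @param hyper a [mixehr_hyper()] (defaults to the one carried by
#'   `estimates`).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model <- function(estimates, hyper = estimates$hyper, path) {
  .check_estimates(estimates)
  obj <- list(
    theta = estimates$theta,
    phi = estimates$phi,
    eta = estimates$eta,
    psi = estimates$psi,
    include_lab_mass = estimates$include_lab_mass,
    hyper = list(alpha = hyper$alpha, beta = hyper$beta, zeta = hyper$zeta,
                 a = hyper$a, b = hyper$b,
                 gamma_prior = lapply(hyper$gamma_prior, function(g)
                   list(shape = unname(g[["shape"]]),
                        rate = unname(g[["rate"]])))))
  ok <- try(jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                                 matrix = "rowmajor"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write model to ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

.check_estimates <- function(est, tol = 1e-6) {
  if (nrow(est$theta) &&
      any(abs(rowSums(est$theta) - 1) > tol))
    stop("invalid estimates: theta rows must sum to 1")
  for (t in seq_along(est$phi))
    if (any(abs(colSums(est$phi[[t]]) - 1) > tol))
      stop("invalid estimates: phi columns must sum to 1 (type ", t, ")")
  for (l in seq_along(est$eta))
    if (any(abs(rowSums(est$eta[[l]]) - 1) > tol))
      stop("invalid estimates: eta rows must sum to 1 (lab ", l, ")")
  if (length(est$psi) && any(est$psi <= 0 | est$psi >= 1))
    stop("invalid estimates: psi must lie strictly in (0, 1)")
  invisible(est)
}

#' Read a fitted model written by [write_model()]
#'
#' @param path file path.
#' @return a `mixehr_estimates` (with `$hyper` restored).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  as_matlist <- function(x) {
    if (is.null(x) || length(x) == 0L) return(list())
    # same-shaped per-type/per-lab matrices simplify to a 3-D array
    if (is.array(x) && length(dim(x)) == 3L)
      return(lapply(seq_len(dim(x)[1L]), function(i)
        matrix(x[i, , ], dim(x)[2L], dim(x)[3L])))
    if (!is.list(x)) return(list(as_mat(x)))
    lapply(x, as_mat)
  }
  gp <- lapply(obj$hyper$gamma_prior, function(g)
    c(shape = as.numeric(g[["shape"]]), rate = as.numeric(g[["rate"]])))
  num_list <- function(x) {
    if (is.null(x) || length(x) == 0L) return(list())
    if (!is.list(x)) list(as.numeric(x)) else lapply(x, as.numeric)
  }
  hyper <- mixehr_hyper(alpha = as.numeric(obj$hyper$alpha),
                        beta = num_list(obj$hyper$beta),
                        zeta = num_list(obj$hyper$zeta),
                        a = as.numeric(obj$hyper$a),
                        b = as.numeric(obj$hyper$b),
                        gamma_prior = gp)
  theta <- obj$theta
  K <- length(hyper$alpha)
  if (is.null(theta) || length(theta) == 0L) theta <- matrix(0, 0L, K)
  psi <- obj$psi
  if (is.null(psi) || length(psi) == 0L) psi <- matrix(0, 0L, K)
  structure(list(theta = as_mat(theta), phi = as_matlist(obj$phi),
                 eta = as_matlist(obj$eta), psi = as_mat(psi),
                 hyper = hyper,
                 include_lab_mass = isTRUE(obj$include_lab_mass)),
            class = "mixehr_estimates")
}
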