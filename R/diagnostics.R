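#' Parameter variance-covariance from the Jacobian at the minimum
#'
#' `V_p = [C / (N_D - N_p)] (J^T W J)^{-1}`.  The weights need only be
#' proportional to the true inverse variances: the reduced-chi-square scale
#' `C / dof` absorbs the unknown proportionality constant, so the covariance
#' is invariant to rescaling all weights.
#'
#' @param J Jacobian at the optimum (`N_D x N_p`).
#' @param weights Diagonal inverse-variance weights (scalar or vector).
#' @param cost_at_min Cost at the optimum.
#' @param n_data Number of data points.
#' @param n_params Number of variable parameters.
#' @return A list of class `covariance_report`: `vcov`, `sigma`, `dof`,
#'   `scale`.
#' @export
ls_covariance <- function(J, weights, cost_at_min, n_data, n_params) {
  if (n_data <= n_params)
    stop("ls_covariance: no degrees of freedom (n_data <= n_params)")
  gram <- crossprod(J * sqrt(weights))
  inv <- tryCatch(solve(gram), error = function(e) NULL)
  if (is.null(inv)) {
    # name the most collinear pair for the error message
    d <- sqrt(diag(gram))
    cors <- gram / outer(d, d)
    diag(cors) <- 0
    idx <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    nm <- colnames(J)
    lbl <- if (is.null(nm)) paste(idx, collapse = ", ")
           else paste(nm[idx], collapse = ", ")
    stop("ls_covariance: singular J^T W J; most collinear pair: ", lbl)
  }
  dof <- n_data - n_params
  scale <- cost_at_min / dof
  vcov <- scale * (inv + t(inv)) / 2
  structure(list(vcov = vcov, sigma = sqrt(pmax(diag(vcov), 0)),
                 dof = dof, scale = scale),
            class = "covariance_report")
}

#' Normal-approximation confidence-interval half-widths
#'
#' `z(level) * sigma` per parameter; normal (not t) quantiles are used since
#' the number of data points vastly exceeds the number of parameters in the
#' intended applications.
#'
#' @param report A `covariance_report` (or any list with `sigma`).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Vector of half-widths (`>= 0`).
#' @export
confidence_intervals <- function(report, level = 0.95) {
  stopifnot(level > 0, level < 1)
  qnorm((1 + level) / 2) * report$sigma
}

#' Variance inflation factors from a (weighted) Jacobian
#'
#' Columns of `J` are normalized so that the weighted Gram matrix has unit
#' diagonal; the VIFs are the diagonal of its true inverse (never a
#' pseudo-inverse, so that perfect collinearity is reported as a blow-up
#' rather than masked).  Values above `1e12`, or a failed inversion, set
#' `condition_flag`.
#'
#' @param J Jacobian (`N_D x N_p`).
#' @param weights Diagonal inverse-variance weights.
#' @param huge Reporting threshold for the condition flag (default `1e12`).
#' @return A list of class `vif_report`: `vif` (each `>= 1` up to numerical
#'   slack), `condition_flag`.
#' @export
vif <- function(J, weights = 1, huge = 1e12) {
  d <- sqrt(colSums(weights * J^2))
  if (any(d == 0)) {
    nm <- colnames(J)
    k <- which(d == 0)[1]
    stop("vif: zero Jacobian column for parameter ",
         if (is.null(nm)) k else nm[k])
  }
  Jn <- sweep(J, 2, d, "/")
  G <- crossprod(Jn * sqrt(weights))
  inv <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(inv)) {
    v <- rep(Inf, ncol(J))
    names(v) <- colnames(J)
    return(structure(list(vif = v, condition_flag = TRUE),
                     class = "vif_report"))
  }
  v <- diag(inv)
  names(v) <- colnames(J)
  structure(list(vif = v,
                 condition_flag = any(!is.finite(v)) || any(v > huge)),
            class = "vif_report")
}

#' First-order propagation of a data perturbation into the fit parameters
#'
#' The linear response of the least-squares optimum to a perturbation `dD`
#' of the data: `dp = (J^T W J)^{-1} J^T W dD`.  For `dD` in the column
#' space of `J` this is the exact projection identity (`dD = J delta` gives
#' `dp = delta`).
#'
#' @param J Jacobian at the optimum.
#' @param weights Diagonal inverse-variance weights.
#' @param dD Data perturbation vector.
#' @return Parameter perturbation vector.
#' @export
perturbation_propagation <- function(J, weights, dD) {
  if (length(dD) != nrow(J)) stop("perturbation_propagation: shape mismatch")
  gram <- crossprod(J * sqrt(weights))
  rhs <- crossprod(J, weights * dD)
  dp <- tryCatch(solve(gram, rhs), error = function(e)
    stop("perturbation_propagation: singular J^T W J"))
  setNames(as.vector(dp), colnames(J))
}
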