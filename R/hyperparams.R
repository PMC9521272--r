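#' Hyperparameters for the ensemble predictor
#'
#' Returns the full hyperparameter set as a validated named list. The
#' defaults are the reference operating point of the method:
#'
#' * `alpha_c`, `alpha_d` (0.5): fusion weights between biological
#'   similarity (functional / semantic) and association-profile similarity
#'   for circRNAs and diseases.
#' * `gamma_c_band`, `gamma_d_band` (1): bandwidth scale of the Gaussian
#'   association-profile kernel; the effective bandwidth divides by the
#'   mean squared profile norm.
#' * `beta` (0.2): weight of the walk term in the restart iteration
#'   p <- beta * t(W) p + (1 - beta) * p0.
#' * `lambda_` (0.1): share of the initial probability mass placed
#'   uniformly on the circRNA side; 1 - lambda_ goes to the seed disease.
#' * `mu` (0.6): probability of jumping between the circRNA and disease
#'   networks along association edges.
#' * `gamma_c_reg` (0.95), `gamma_d_reg` (0.2): Laplacian regularization
#'   trade-offs in circRNA and disease space.
#' * `theta` (0.3): soft-voting weight of the Laplacian RLS scores in the
#'   ensemble Ypre = P + theta * F.
#' * `rwr_tol` (1e-6), `rwr_max_iter` (1000): l1 stopping rule of the
#'   restart iteration.
#'
#' @param ... named overrides of any of the fields above
#' @return a named list of class `cdaParams`
#' @seealso [readParamsConfig()]
#' @examples
#' cdaParams()
#' cdaParams(theta = 0.5, mu = 0.4)
#' @export
cdaParams <- function(...) {
    p <- list(alpha_c = 0.5, alpha_d = 0.5,
              gamma_c_band = 1, gamma_d_band = 1,
              beta = 0.2, lambda_ = 0.1, mu = 0.6,
              gamma_c_reg = 0.95, gamma_d_reg = 0.2,
              theta = 0.3,
              rwr_tol = 1e-6, rwr_max_iter = 1000L)
    dots <- list(...)
    if (length(dots)) {
        if (is.null(names(dots)) || any(!nzchar(names(dots))))
            stop("all hyperparameter overrides must be named")
        unknown <- setdiff(names(dots), names(p))
        if (length(unknown))
            stop("unknown hyperparameter(s): ", paste(unknown, collapse = ", "))
        p[names(dots)] <- dots
    }
    .validateParams(p)
    class(p) <- "cdaParams"
    p
}

.validateParams <- function(p) {
    chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
    num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
    for (f in c("alpha_c", "alpha_d", "gamma_c_band", "gamma_d_band", "beta",
                "lambda_", "mu", "gamma_c_reg", "gamma_d_reg", "theta",
                "rwr_tol"))
        chk(num1(p[[f]]), sprintf("'%s' must be a single finite number", f))
    chk(p$alpha_c >= 0 && p$alpha_c <= 1, "'alpha_c' must lie in [0, 1]")
    chk(p$alpha_d >= 0 && p$alpha_d <= 1, "'alpha_d' must lie in [0, 1]")
    chk(p$gamma_c_band > 0, "'gamma_c_band' must be positive")
    chk(p$gamma_d_band > 0, "'gamma_d_band' must be positive")
    chk(p$beta > 0 && p$beta < 1, "'beta' must lie in (0, 1)")
    chk(p$lambda_ >= 0 && p$lambda_ <= 1, "'lambda_' must lie in [0, 1]")
    chk(p$mu > 0 && p$mu < 1, "'mu' must lie in (0, 1)")
    chk(p$gamma_c_reg >= 0, "'gamma_c_reg' must be nonnegative")
    chk(p$gamma_d_reg >= 0, "'gamma_d_reg' must be nonnegative")
    chk(p$theta >= 0, "'theta' must be nonnegative")
    chk(p$rwr_tol > 0, "'rwr_tol' must be positive")
    chk(num1(p$rwr_max_iter) && p$rwr_max_iter >= 1 &&
            p$rwr_max_iter == round(p$rwr_max_iter),
        "'rwr_max_iter' must be a positive integer")
    invisible(p)
}

#' Read hyperparameters from a flat YAML config file
#'
#' The config is a flat key/value document whose keys mirror the
#' [cdaParams()] field names; keys absent from the file keep their
#' defaults. Unknown keys are an error so that typos do not silently fall
#' back to defaults.
#'
#' @param path path to a YAML file
#' @return a `cdaParams` list
#' @export
readParamsConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg))
        stop("config must be a flat key/value mapping")
    do.call(cdaParams, cfg)
}

#' @export
print.cdaParams <- function(x, ...) {
    cat("cdaNetFuse hyperparameters:\n")
    for (f in names(x))
        cat(sprintf("  %-13s %s\n", f, format(x[[f]])))
    invisible(x)
}
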