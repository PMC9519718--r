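#' Tidy a fitted MET model
#'
#' @param x A `met_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated variance parameter: `term`,
#'   `estimate`, `component` (`genetic`, `block`, `residual`, `env`).
#' @export
tidy.met_fit <- function(x, ...) {
  ng <- x$m_genetic
  p <- x$p
  comp <- c(rep("genetic", ng), rep("block", p), rep("residual", p),
            if (!is.null(x$sigma2_omega)) "env")
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 component = comp)
}

#' @rdname tidy.met_fit
#' @return `glance()` returns a one-row tibble: `logLik`, `AIC`,
#'   `n_par_genetic`, `m_total`, `iterations`, `converged`, `n`, `p`, `v`.
#' @export
glance.met_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic,
                 n_par_genetic = x$m_genetic, m_total = x$m_total,
                 iterations = x$iterations, converged = x$converged,
                 n = x$n, p = x$p, v = x$v)
}

#' @rdname tidy.met_fit
#' @return `augment()` returns the EBLUP GE effects, one row per genotype by
#'   environment: `genotype`, `env`, `blup`.
#' @export
augment.met_fit <- function(x, ...) {
  tibble::tibble(genotype = rep(x$genotypes, x$p),
                 env = rep(x$envs, each = x$v),
                 blup = as.numeric(x$Umat))
}

#' Tidy a rotated factor solution
#'
#' @param x A `met_rotation`.
#' @param ... Unused.
#' @return Long tibble of rotated composite loadings: `env`, `factor`,
#'   `loading`, plus `psi` per environment.
#' @export
tidy.met_rotation <- function(x, ...) {
  k <- length(x$d)
  out <- tibble::tibble(env = rep(x$envs, k),
                        factor = rep(seq_len(k), each = x$p),
                        loading = as.numeric(x$Lambda))
  out$psi <- rep(x$psi, k)
  out
}

#' @rdname tidy.met_rotation
#' @export
glance.met_rotation <- function(x, ...) {
  tibble::tibble(k = length(x$d), d1 = x$d[1L],
                 trace_common = sum(x$d),
                 trace_Ge = sum(diag(x$Ge)))
}

#' Tidy cross-validation accuracies
#'
#' @param x A `met_cv`.
#' @param ... Unused.
#' @return The per-environment accuracy tibble.
#' @export
tidy.met_cv <- function(x, ...) x$accuracy

#' @rdname tidy.met_cv
#' @export
glance.met_cv <- function(x, ...) {
  r <- x$accuracy$accuracy
  tibble::tibble(mode = x$mode, n_env = nrow(x$accuracy),
                 min = suppressWarnings(min(r, na.rm = TRUE)),
                 mean = mean(r, na.rm = TRUE),
                 max = suppressWarnings(max(r, na.rm = TRUE)))
}
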