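# General REML likelihood evaluator via the mixed model equations.
# Handles arbitrary (unbalanced, missing-plot) designs; cost grows with
# (v * p)^3, so it is the engine of choice at small to moderate scale.
# The balanced-design evaluator in reml_fast.R computes the same quantities.

evaluator_dense <- function(frame) {
  n <- frame$n; p <- frame$p; v <- frame$v; NB <- frame$NB
  env <- frame$env; geno <- frame$geno; block <- frame$block
  y <- frame$y
  px <- frame$px
  Xsp <- Matrix::Matrix(frame$Xe[env, , drop = FALSE], sparse = TRUE)
  Zb <- Matrix::sparseMatrix(i = seq_len(n), j = block, x = 1, dims = c(n, NB))
  Zw <- if (frame$use_omega)
    Matrix::sparseMatrix(i = seq_len(n), j = env, x = 1, dims = c(n, p)) else NULL
  iu_col <- (env - 1L) * v + geno
  Zu <- Matrix::sparseMatrix(i = seq_len(n), j = iu_col, x = 1, dims = c(n, v * p))
  W_all <- if (frame$use_omega) cbind(Xsp, Zb, Zw, Zu) else cbind(Xsp, Zb, Zu)
  nw <- if (frame$use_omega) p else 0L
  ix <- seq_len(px)
  ib <- px + seq_len(NB)
  iw <- if (frame$use_omega) px + NB + seq_len(p) else integer(0)
  iu <- px + NB + nw + seq_len(v * p)
  dim_c <- px + NB + nw + v * p
  rows_of <- function(j) (j - 1L) * v + seq_len(v)

  layout <- frame$layout
  Gg <- frame$Gg; Gg_inv <- frame$Gg_inv

  function(theta, derivs = TRUE) {
    th <- split_theta(frame, theta)
    Ge <- layout$Ge(th$g)
    cGe <- tryCatch(chol(Ge), error = function(e) NULL)
    if (is.null(cGe) || min(diag(cGe))^2 < 1e-12 * max(diag(Ge))) {
      return(list(ok = FALSE))
    }
    Ge_inv <- chol2inv(cGe)
    logdet_Ge <- 2 * sum(log(diag(cGe)))
    Gu_inv <- kronecker(Ge_inv, Gg_inv)

    w <- 1 / th$se2[env]
    Ws <- W_all * sqrt(w)
    C <- as.matrix(Matrix::crossprod(Ws))
    diag(C)[ib] <- diag(C)[ib] + 1 / th$sb2[frame$block_env]
    if (frame$use_omega) diag(C)[iw] <- diag(C)[iw] + 1 / th$sw2
    C[iu, iu] <- C[iu, iu] + Gu_inv
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE))

    rhs <- as.numeric(Matrix::crossprod(W_all, w * y))
    sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    yPy <- sum(w * y^2) - sum(rhs * sol)
    logdet_C <- 2 * sum(log(diag(ch)))
    logdet_R <- sum(frame$n_j * log(th$se2))
    logdet_G <- v * logdet_Ge + p * frame$logdet_Gg +
      sum(frame$nb_j * log(th$sb2)) +
      (if (frame$use_omega) p * log(th$sw2) else 0)
    ll <- -0.5 * (yPy + logdet_R + logdet_G + logdet_C +
                    (n - px) * log(2 * pi))

    tau <- sol[ix]
    Umat <- matrix(sol[iu], v, p)
    out <- list(ok = TRUE, ll = ll, tau = tau,
                beta = sol[ib], omega = if (frame$use_omega) sol[iw],
                Umat = Umat, Ge = Ge, Ge_inv = Ge_inv, yPy = yPy)
    if (!derivs) return(out)

    Cinv <- chol2inv(ch)
    ehat <- y - as.numeric(W_all %*% sol)
    Py <- w * ehat

    # u'P y folded to a v x p matrix
    Utp <- matrix(0, v, p)
    agg <- rowsum(Py, group = iu_col)
    Utp[as.integer(rownames(agg))] <- agg

    # traces against the genetic blocks
    Cuu <- Cinv[iu, iu]
    Tm <- Gu_inv %*% Cuu %*% Gu_inv
    S_gg <- matrix(0, p, p)
    for (j in seq_len(p)) for (j2 in j:p) {
      S_gg[j, j2] <- S_gg[j2, j] <- sum(Gg * Tm[rows_of(j), rows_of(j2)])
    }

    dGe <- layout$dGe(th$g)
    ng <- length(frame$idx_g)
    n_par <- frame$n_par
    trs <- numeric(n_par)
    Wai <- matrix(0, n, n_par)
    for (a in seq_len(ng)) {
      D <- dGe[[a]]
      trs[a] <- v * sum(D * Ge_inv) - sum(D * S_gg)
      Wm <- Gg %*% Utp %*% D
      Wai[, a] <- Wm[cbind(geno, env)]
    }
    # block variances
    pb <- numeric(NB)
    aggb <- rowsum(Py, group = block)
    pb[as.integer(rownames(aggb))] <- aggb
    dCb <- diag(Cinv)[ib]
    for (j in seq_len(p)) {
      a <- frame$idx_b[j]
      sel <- frame$block_env == j
      trs[a] <- sum(sel) / th$sb2[j] - sum(dCb[sel]) / th$sb2[j]^2
      Wai[, a] <- ifelse(frame$block_env[block] == j, pb[block], 0)
    }
    # residual variances need diag(P)
    qdiag <- Matrix::rowSums((W_all %*% Cinv) * W_all)
    diagP <- w - w^2 * qdiag
    for (j in seq_len(p)) {
      a <- frame$idx_e[j]
      sel <- env == j
      trs[a] <- sum(diagP[sel])
      Wai[, a] <- ifelse(sel, Py, 0)
    }
    if (frame$use_omega) {
      a <- frame$idx_w
      pe <- as.numeric(rowsum(Py, group = factor(env, levels = seq_len(p))))
      trs[a] <- p / th$sw2 - sum(diag(Cinv)[iw]) / th$sw2^2
      Wai[, a] <- pe[env]
    }

    # scores and average information
    score <- -0.5 * (trs - as.numeric(crossprod(Wai, Py)))
    Rw <- w * Wai
    T1 <- as.matrix(Matrix::crossprod(W_all, Rw))
    T2 <- backsolve(ch, backsolve(ch, T1, transpose = TRUE))
    PW <- Rw - w * as.matrix(W_all %*% T2)
    AI <- 0.5 * crossprod(Wai, PW)
    AI <- (AI + t(AI)) / 2

    c(out, list(score = score, AI = AI))
  }
}
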