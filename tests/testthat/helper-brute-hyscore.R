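# Independent brute-force 4-pulse HYSCORE: explicit density-matrix
# propagation through pi/2-tau-pi/2-t1-pi-t2-pi/2-tau with a four-step
# phase cycle and a four-point electron-offset comb, normalized against
# the uncoupled system.  Deliberately written from the pulse sequence, not
# from the engine's trace formulas.
brute_hyscore <- function(system, timing, orient, field) {
  PH <- 2e-3 * pi
  entries <- list()
  for (e in system$nuclei)
    for (i in seq_len(e$nucleus$count)) entries <- c(entries, list(e))
  dims <- c(2L, vapply(entries, function(e) as.integer(2 * e$nucleus$I + 1),
                       integer(1)))
  D <- prod(dims)
  sop <- function(I) {
    d <- as.integer(round(2 * I + 1)); m <- seq(I, -I, by = -1)
    Ip <- matrix(0, d, d)
    for (j in seq_len(d - 1))
      Ip[j, j + 1] <- sqrt(I * (I + 1) - m[j + 1] * (m[j + 1] + 1))
    list(x = (Ip + t(Ip)) / 2, y = (Ip - t(Ip)) / (2i), z = diag(m) + 0i)
  }
  emb <- function(op, pos) {
    mats <- lapply(seq_along(dims), function(j)
      if (j == pos) op else diag(dims[j]) + 0i)
    Reduce(kronecker, mats)
  }
  es <- sop(0.5)
  Sx <- emb(es$x, 1); Sy <- emb(es$y, 1); Sz <- emb(es$z, 1)
  Sp <- Sx + 1i * Sy
  n <- c(sin(orient$theta) * cos(orient$phi),
         sin(orient$theta) * sin(orient$phi), cos(orient$theta))
  rot <- function(eu) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
    Rz(eu[1]) %*% Ry(eu[2]) %*% Rz(eu[3])
  }
  H_nuc <- function(couplings) {
    H <- matrix(0i, D, D)
    for (j in seq_along(entries)) {
      e <- entries[[j]]; ops <- sop(e$nucleus$I)
      Ix <- emb(ops$x, j + 1); Iy <- emb(ops$y, j + 1); Iz <- emb(ops$z, j + 1)
      nz <- abs(e$nucleus$gamma_MHz_T) * field$B0_gauss * 1e-4
      H <- H - nz * (n[1] * Ix + n[2] * Iy + n[3] * Iz)
      if (!couplings) next
      hf <- e$hyperfine
      Apv <- diag(c(hf$A_iso - hf$T_dip, hf$A_iso - hf$T_dip,
                    hf$A_iso + 2 * hf$T_dip))
      R <- rot(hf$euler)
      a <- as.numeric(n %*% (R %*% Apv %*% t(R)))
      H <- H + (a[1] * Ix + a[2] * Iy + a[3] * Iz) %*% Sz
      q <- e$quadrupole
      if (!is.null(q) && q$K > 0) {
        Rq <- rot(q$euler)
        Iq <- lapply(1:3, function(m)
          Rq[1, m] * Ix + Rq[2, m] * Iy + Rq[3, m] * Iz)
        H <- H + q$K * (3 * Iq[[3]] %*% Iq[[3]] -
                          e$nucleus$I * (e$nucleus$I + 1) * diag(D) +
                          q$eta * (Iq[[1]] %*% Iq[[1]] - Iq[[2]] %*% Iq[[2]]))
      }
    }
    H
  }
  pulse <- function(ang, ph) {
    G <- ang * (Sx * cos(ph) + Sy * sin(ph))
    eg <- eigen(G, symmetric = TRUE)
    eg$vectors %*% (exp(-1i * eg$values) * Conj(t(eg$vectors)))
  }
  tau <- timing$tau_ns
  t1v <- timing$t_start_ns + timing$dt_ns * (0:(timing$n1 - 1))
  t2v <- timing$t_start_ns + timing$dt_ns * (0:(timing$n2 - 1))
  offsets <- (0:3) / (8e-3 * tau)
  Px <- pulse(pi / 2, 0); Pmx <- pulse(pi / 2, pi); Ppi <- pulse(pi, 0)
  run <- function(H0) {
    sig <- matrix(0i, length(t1v), length(t2v))
    for (off in offsets) {
      H <- H0 + off * Sz
      eg <- eigen(H, symmetric = TRUE); V <- eg$vectors; lam <- eg$values
      prop <- function(t) V %*% (exp(-1i * PH * lam * t) * Conj(t(V)))
      Ut <- prop(tau)
      K <- Conj(t(Px)) %*% Conj(t(Ut)) %*% Sp %*% Ut %*% Px
      Kp <- Conj(t(V)) %*% K %*% V
      frq <- as.vector(outer(lam, lam, function(x, y) y - x))
      ph2 <- exp(1i * PH * outer(frq, t2v))
      for (i1 in 1:2) for (i2 in 1:2) {
        rec <- if (i1 == i2) 1 else -1
        P1 <- if (i1 == 1) Px else Pmx
        P2 <- if (i2 == 1) Px else Pmx
        rho2 <- P2 %*% Ut %*% P1 %*% Sz %*% Conj(t(P1)) %*%
          Conj(t(Ut)) %*% Conj(t(P2))
        for (a in seq_along(t1v)) {
          U1 <- prop(t1v[a])
          A1 <- Ppi %*% U1 %*% rho2 %*% Conj(t(U1)) %*% Conj(t(Ppi))
          cf <- as.vector((Conj(t(V)) %*% A1 %*% V) * t(Kp))
          sig[a, ] <- sig[a, ] + rec * as.vector(cf %*% ph2)
        }
      }
    }
    sig
  }
  Re(run(H_nuc(TRUE)) / run(H_nuc(FALSE)))
}
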