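# Deliberately naive, straight-line reimplementations of the models,
# written as literal term-by-term loops over the defining equations.  They
# share no code with the package internals and serve as independent
# oracles on small systems.

oracle_average_charges <- function(mol, r_ave = 0.81764) {
  seg <- mol$segments
  n <- nrow(seg)
  out <- numeric(n)
  for (m in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      rn2 <- seg$area[k] / pi
      d2 <- (seg$x[m] - seg$x[k])^2 + (seg$y[m] - seg$y[k])^2 +
        (seg$z[m] - seg$z[k])^2
      f <- (r_ave^2 * rn2 / (r_ave^2 + rn2)) * exp(-d2 / (r_ave^2 + rn2))
      num <- num + seg$charge_density[k] * f
      den <- den + f
    }
    out[m] <- num / den
  }
  out
}

oracle_sg_combinatorial <- function(x, r, q, z = 10) {
  k <- length(x)
  theta <- x * q / sum(x * q)
  phi <- x * r / sum(x * r)
  l <- (z / 2) * (r - q) - (r - 1)
  out <- numeric(k)
  for (i in seq_len(k)) {
    out[i] <- log(phi[i] / x[i]) + (z / 2) * q[i] * log(theta[i] / phi[i]) +
      l[i] - (phi[i] / x[i]) * sum(x * l)
  }
  out
}

oracle_dW_2002 <- function(sm, sn, p) {
  acc <- max(sm, sn); don <- min(sm, sn)
  (p$alpha_prime / 2) * (sm + sn)^2 +
    p$c_hb * max(0, acc - p$sigma_hb) * min(0, don + p$sigma_hb)
}

oracle_segment_gamma <- function(p_vec, W, T, R = 0.001987, iters = 2000L) {
  nb <- length(p_vec)
  gam <- rep(1, nb)
  for (it in seq_len(iters)) {
    new <- numeric(nb)
    for (m in seq_len(nb)) {
      s <- 0
      for (n in seq_len(nb)) {
        s <- s + p_vec[n] * gam[n] * exp(-W[m, n] / (R * T))
      }
      new[m] <- 1 / s
    }
    if (max(abs(new - gam)) < 1e-13) { gam <- new; break }
    gam <- (gam + new) / 2
  }
  gam
}

# full 2002 model: components as list(A=, V=, p=<51 probs>)
oracle_cosmosac2002 <- function(comps, x, T, p = cosmopharm::cosmosac2002_params()) {
  grid <- seq(-0.025, 0.025, by = 0.001)
  nb <- length(grid)
  k <- length(comps)
  A <- sapply(comps, `[[`, "A")
  V <- sapply(comps, `[[`, "V")
  r <- V / p$r0; q <- A / p$q0; n_i <- A / p$a_eff
  W <- matrix(0, nb, nb)
  for (m in seq_len(nb)) for (n in seq_len(nb)) {
    W[m, n] <- oracle_dW_2002(grid[m], grid[n], p)
  }
  p_mix <- numeric(nb)
  for (b in seq_len(nb)) {
    num <- 0; den <- 0
    for (i in seq_len(k)) {
      num <- num + x[i] * A[i] * comps[[i]]$p[b]
      den <- den + x[i] * A[i]
    }
    p_mix[b] <- num / den
  }
  gam_S <- oracle_segment_gamma(p_mix, W, T, p$R)
  comb <- oracle_sg_combinatorial(x, r, q, p$z)
  out <- numeric(k)
  for (i in seq_len(k)) {
    gam_i <- oracle_segment_gamma(comps[[i]]$p, W, T, p$R)
    res <- 0
    for (b in seq_len(nb)) {
      res <- res + comps[[i]]$p[b] * (log(gam_S[b]) - log(gam_i[b]))
    }
    out[i] <- comb[i] + n_i[i] * res
  }
  out
}

oracle_dW_2010 <- function(sm, sn, tm, tn, T, p) {
  es <- (p$A_ES + p$B_ES / T^2) * (sm + sn)^2
  chb <- 0
  if (sm * sn < 0) {
    if (tm == "OH" && tn == "OH") chb <- p$c_OH_OH
    if (tm == "OT" && tn == "OT") chb <- p$c_OT_OT
    if ((tm == "OH" && tn == "OT") || (tm == "OT" && tn == "OH")) chb <- p$c_OH_OT
  }
  es + p$hb_sign * chb * (sm - sn)^2
}

# 2010 model: components as list(A=, V=, nhb=, oh=, ot=) each a 51-vector
oracle_cosmosac2010 <- function(comps, x, T, p = cosmopharm::cosmosac2010_params()) {
  grid <- seq(-0.025, 0.025, by = 0.001)
  nb <- length(grid)
  sig <- c(grid, grid, grid)
  cls <- c(rep("NHB", nb), rep("OH", nb), rep("OT", nb))
  N <- 3L * nb
  k <- length(comps)
  A <- sapply(comps, `[[`, "A")
  V <- sapply(comps, `[[`, "V")
  r <- V / p$r0; q <- A / p$q0; n_i <- A / p$a_eff
  W <- matrix(0, N, N)
  for (m in seq_len(N)) {
    W[m, ] <- sapply(seq_len(N), function(n) {
      oracle_dW_2010(sig[m], sig[n], cls[m], cls[n], T, p)
    })
  }
  stack <- function(cc) c(cc$nhb, cc$oh, cc$ot)
  p_mix <- numeric(N)
  for (b in seq_len(N)) {
    num <- 0; den <- 0
    for (i in seq_len(k)) {
      num <- num + x[i] * A[i] * stack(comps[[i]])[b]
      den <- den + x[i] * A[i]
    }
    p_mix[b] <- num / den
  }
  gam_S <- oracle_segment_gamma(p_mix, W, T, p$R, iters = 3000L)
  comb <- oracle_sg_combinatorial(x, r, q, p$z)
  out <- numeric(k)
  for (i in seq_len(k)) {
    pi_ <- stack(comps[[i]])
    gam_i <- oracle_segment_gamma(pi_, W, T, p$R, iters = 3000L)
    out[i] <- comb[i] + n_i[i] * sum(pi_ * (log(gam_S) - log(gam_i)))
  }
  out
}

# literal triple-loop Flory-Huggins
oracle_flory_huggins <- function(x, df, T, convention = "per-volume") {
  k <- nrow(df)
  V <- df$V
  phi <- x * V / sum(x * V)
  chi <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    chi[i, j] <- V[i] / (8.314 * T) *
      ((df$delta_d[i] - df$delta_d[j])^2 +
         0.25 * (df$delta_p[i] - df$delta_p[j])^2 +
         0.25 * (df$delta_h[i] - df$delta_h[j])^2)
    if (convention == "per-volume") chi[i, j] <- chi[i, j] / V[i]
  }
  out <- numeric(k)
  for (i in seq_len(k)) {
    t3 <- 0
    for (j in seq_len(k)) t3 <- t3 + chi[i, j] * phi[j]^2
    t4 <- 0
    for (j in seq_len(k)) for (m in seq_len(k)) {
      t4 <- t4 + phi[j] * phi[m] * chi[j, m]
    }
    out[i] <- log(phi[i] / x[i]) + 1 - phi[i] / x[i] + 2 * V[i] * t3 - V[i] * t4
  }
  out
}

# vectorized closed-form binary FH ln gamma of component 1 (per-volume),
# used by the solubility grid-scan oracle
oracle_fh_binary_lng1 <- function(x1, df, T) {
  V1 <- df$V[1L]; V2 <- df$V[2L]
  kern <- 1 / (8.314 * T) *
    ((df$delta_d[1L] - df$delta_d[2L])^2 +
       0.25 * (df$delta_p[1L] - df$delta_p[2L])^2 +
       0.25 * (df$delta_h[1L] - df$delta_h[2L])^2)
  vbar <- x1 * V1 + (1 - x1) * V2
  phi1 <- x1 * V1 / vbar
  phi2 <- 1 - phi1
  log(V1 / vbar) + 1 - V1 / vbar + 2 * V1 * kern * phi2^2 -
    V1 * 2 * phi1 * phi2 * kern
}

# package component -> plain list the oracles accept
as_oracle_comp <- function(comp) {
  list(A = comp$area, V = comp$volume, p = comp$profile$p,
       nhb = comp$split$nhb, oh = comp$split$oh, ot = comp$split$ot)
}
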