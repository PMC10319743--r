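# Integer-order Bessel and Hankel functions of complex argument.
#
# The cylindrical mode-matching solver needs J_n(z) and H^(1)_n(z) for complex
# z (lossy media: Im z >= 0) at orders up to a few tens and |z| up to ~1e3.
# Base R's besselJ/besselY are real-argument only, so these are computed here:
#   * J_n: Miller's downward recurrence, normalised by J_0 + 2 sum J_{2k} = 1
#     (valid for all complex z); stable for every order and argument size.
#   * H^(1)_0, H^(1)_1: Neumann series (moderate |z|) or the large-argument
#     asymptotic expansion (|z| > 25), then stable upward recurrence
#     H_{n+1} = (2n/z) H_n - H_{n-1}.
# Derivatives use Z'_n = (Z_{n-1} - Z_{n+1}) / 2 and Z'_0 = -Z_1.
# Accuracy is checked in the tests against frozen independent reference values
# and the Wronskian J_n(z) H'_n(z) - J'_n(z) H_n(z) = 2i / (pi z).

# J_0 .. J_nmax at a single complex z. Returns complex vector length nmax + 1.
bw_besselJ <- function(nmax, z) {
  stopifnot(nmax >= 0, length(z) == 1L)
  z <- as.complex(z)
  if (z == 0) return(c(1 + 0i, rep(0 + 0i, nmax)))
  az <- Mod(z)
  # start order high enough that the trial solution is dominated by J
  m0 <- max(nmax, ceiling(az)) + 15L + ceiling(10 * sqrt(max(nmax, az)))
  if (m0 %% 2L == 1L) m0 <- m0 + 1L
  jp <- 0 + 0i       # J_{m+1} trial
  jc <- 1e-30 + 0i   # J_m trial
  out <- rep(NA_complex_, nmax + 1L)
  norm <- 0 + 0i
  for (m in seq(m0, 0L)) {
    jm <- (2 * (m + 1) / z) * jc - jp   # J_m from J_{m+1}, J_{m+2}
    jp <- jc
    jc <- jm
    if (m <= nmax) out[m + 1L] <- jc
    if (m > 0L && m %% 2L == 0L) norm <- norm + 2 * jc
    # rescale to avoid overflow of the unnormalised recurrence
    if (Mod(jc) > 1e250) {
      s <- 1e-250
      jc <- jc * s; jp <- jp * s; norm <- norm * s
      out <- out * s
    }
  }
  norm <- norm + jc   # + J_0
  out / norm
}

# H^(1)_0 .. H^(1)_nmax at a single complex z.
bw_besselH1 <- function(nmax, z) {
  stopifnot(nmax >= 0, length(z) == 1L)
  z <- as.complex(z)
  if (z == 0) abort("H^(1)_n is singular at z = 0.")
  # crossover at |z| = 15: the Neumann series loses ~exp(|z|) of precision to
  # cancellation while the n <= 1 asymptotic error is ~exp(-2|z|) there
  h01 <- if (Mod(z) > 15) h1_asymptotic(z) else h1_series(z)
  out <- rep(NA_complex_, nmax + 1L)
  out[1L] <- h01[1L]
  if (nmax >= 1L) out[2L] <- h01[2L]
  if (nmax >= 2L) {
    for (n in 1L:(nmax - 1L)) {
      out[n + 2L] <- (2 * n / z) * out[n + 1L] - out[n]
    }
  }
  out
}

# Neumann-series H^(1)_0, H^(1)_1 for moderate |z| (A&S 9.1.11 with n = 0, 1).
h1_series <- function(z) {
  egamma <- 0.57721566490153286060651209008240243
  # J series terms reused for Y
  kmax <- 60L
  q <- (z / 2)^2
  # J0, J1 by direct series (moderate |z|, fine)
  term <- 1 + 0i; j0 <- term
  for (k in 1:kmax) {
    term <- term * (-q) / (k * k)
    j0 <- j0 + term
    if (Mod(term) < 1e-18 * Mod(j0)) break
  }
  term <- (z / 2); j1 <- term
  for (k in 1:kmax) {
    term <- term * (-q) / (k * (k + 1))
    j1 <- j1 + term
    if (Mod(term) < 1e-18 * Mod(j1)) break
  }
  lz <- log(z / 2)
  # Y0 = (2/pi)[ (ln(z/2)+gamma) J0 + sum_{k>=1} (-1)^{k+1} Hk q^k/(k!)^2 ]
  s <- 0 + 0i; term <- 1 + 0i; hk <- 0
  for (k in 1:kmax) {
    term <- term * q / (k * k)
    hk <- hk + 1 / k
    add <- (-1)^(k + 1) * hk * term
    s <- s + add
    if (Mod(add) < 1e-18 * max(Mod(s), 1e-300)) break
  }
  y0 <- (2 / pi) * ((lz + egamma) * j0 + s)
  # Y1 (A&S 9.1.11, n = 1): (2/pi) ln(z/2) J1 - (2/(pi z))
  #   - (z/(2 pi)) sum_k (-1)^k [psi(k+1)+psi(k+2)] q^k / (k! (k+1)!)
  s <- 0 + 0i; term <- 1 + 0i; psik <- -egamma  # psi(1)
  for (k in 0:kmax) {
    psik1 <- psik + 1 / (k + 1)                 # psi(k+2)
    add <- (-1)^k * (psik + psik1) * term
    s <- s + add
    if (k > 2 && Mod(add) < 1e-18 * max(Mod(s), 1e-300)) break
    term <- term * q / ((k + 1) * (k + 2))
    psik <- psik1
  }
  y1 <- (2 / pi) * lz * j1 - 2 / (pi * z) - (z / (2 * pi)) * s
  c(j0 + 1i * y0, j1 + 1i * y1)
}

# Large-argument asymptotic H^(1)_0, H^(1)_1 (A&S 9.2.7); |z| > 25.
h1_asymptotic <- function(z) {
  vapply(c(0, 1), function(n) {
    mu <- 4 * n^2
    a <- 1 + 0i
    s <- a
    for (k in 1:30) {
      a <- a * (mu - (2 * k - 1)^2) / (k * 8 * z) * 1i
      if (Mod(a) < 1e-18 * Mod(s) || Mod(a) > 1) break
      s <- s + a
    }
    sqrt(2 / (pi * z)) * exp(1i * (z - n * pi / 2 - pi / 4)) * s
  }, complex(1))
}

# Values and derivatives of J and H^(1) for orders 0..nmax at complex z.
# Returns list(J, Jp, H, Hp), each a complex vector of length nmax + 1.
bw_cyl_funs <- function(nmax, z) {
  J <- bw_besselJ(nmax + 1L, z)
  H <- bw_besselH1(nmax + 1L, z)
  idx <- seq_len(nmax + 1L)
  Jp <- c(-J[2L], if (nmax >= 1L) (J[idx[-length(idx)]] - J[idx[-1L] + 1L]) / 2)
  Hp <- c(-H[2L], if (nmax >= 1L) (H[idx[-length(idx)]] - H[idx[-1L] + 1L]) / 2)
  list(J = J[idx], Jp = Jp, H = H[idx], Hp = Hp)
}

# Single-order convenience accessors.
bw_J <- function(n, z) bw_besselJ(n, z)[n + 1L]
bw_H1 <- function(n, z) bw_besselH1(n, z)[n + 1L]
bw_Jp <- function(n, z) {
  if (n == 0L) return(-bw_J(1L, z))
  j <- bw_besselJ(n + 1L, z)
  (j[n] - j[n + 2L]) / 2
}
bw_H1p <- function(n, z) {
  if (n == 0L) return(-bw_H1(1L, z))
  h <- bw_besselH1(n + 1L, z)
  (h[n] - h[n + 2L]) / 2
}
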