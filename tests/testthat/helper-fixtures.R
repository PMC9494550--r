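# shared fixtures, built in code

# a two-delta spectrum: all fluence in two bins far apart in energy
two_delta_spectrum <- function(f1 = 1, f2 = 1) {
  edges <- lethargy_grid(1e-9, 240)
  fl <- rep(0, length(edges) - 1)
  e_rep <- sqrt(edges[-length(edges)] * edges[-1])
  fl[which.min(abs(e_rep - 1e-8))] <- f1   # thermal bin
  fl[which.min(abs(e_rep - 100))] <- f2    # high-energy bin
  neutron_spectrum(edges, fl)
}

# a flat conversion table (h* constant), handy for hand-computable sums
flat_conversion <- function(h = 100) {
  conversion_table(c(1e-10, 1e4), c(h, h))
}

# brute-force oracle for the convolution sums, written independently of the
# production code: plain loops over bins, linear interpolation done by hand
# in log-log space
oracle_h10 <- function(spectrum, table) {
  total <- 0
  for (i in seq_len(nrow(spectrum))) {
    f <- spectrum$fluence_per_cm2_per_Gy[i]
    if (f == 0) next
    e <- sqrt(spectrum$e_low_MeV[i] * spectrum$e_high_MeV[i])
    total <- total + f * oracle_interp(e, table$energy_MeV, table$h10_pSv_cm2)
  }
  total * 1e-6
}

oracle_expected_response <- function(spectrum, rf, table) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(spectrum))) {
    f <- spectrum$fluence_per_cm2_per_Gy[i]
    if (f == 0) next
    e <- sqrt(spectrum$e_low_MeV[i] * spectrum$e_high_MeV[i])
    h <- oracle_interp(e, table$energy_MeV, table$h10_pSv_cm2)
    ec <- min(max(e, min(rf$table$energy_MeV)), max(rf$table$energy_MeV))
    r <- oracle_interp(ec, rf$table$energy_MeV, rf$table$response)
    num <- num + f * h * r
    den <- den + f * h
  }
  num / den
}

oracle_interp <- function(x, xp, yp) {
  if (x <= xp[1]) j <- 1 else if (x >= xp[length(xp)]) j <- length(xp) - 1 else
    j <- max(which(xp <= x))
  j <- min(j, length(xp) - 1)
  t <- (log(x) - log(xp[j])) / (log(xp[j + 1]) - log(xp[j]))
  if (yp[j] > 0 && yp[j + 1] > 0) {
    exp((1 - t) * log(yp[j]) + t * log(yp[j + 1]))
  } else {
    (1 - t) * yp[j] + t * yp[j + 1]
  }
}

# independently coded piecewise quality-factor oracle (scalar, if/else)
oracle_q <- function(y) {
  if (y < 10) return(1)
  if (y <= 100) return(0.32 * y - 2.2)
  300 / sqrt(y)
}

# small campaign from a known model, optionally noise-free
make_campaign <- function(seed, noise = 0.15) {
  generate_campaign(campaign_design(seed = seed, noise_sd = noise))
}
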