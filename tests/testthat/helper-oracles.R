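# Independent oracles for the isotopomer forward model.  These are written
# as explicit enumerations (multinomial partitions with factorial
# coefficients, outer-product offset accumulation) so they share no code
# path with the package's truncated-convolution implementation.

# pmf of the summed mass offset of `count` atoms of one element by explicit
# enumeration of isotope-count partitions (multinomial coefficients).
oracle_element_pmf <- function(probs, count) {
  m <- length(probs)
  res <- numeric(count * (m - 1) + 1)
  rec <- function(i, left, coef, offset) {
    if (i == m) {
      # remaining atoms all take the last isotope (offset m - 1 each)
      o <- offset + (m - 1) * left
      res[o + 1] <<- res[o + 1] + coef * probs[m]^left
      return(invisible(NULL))
    }
    for (n_i in 0:left) {
      rec(i + 1, left - n_i, coef * choose(left, n_i) * probs[i]^n_i,
          offset + (i - 1) * n_i)
    }
  }
  rec(1, count, 1, 0)
  res
}

# combine two offset pmfs by outer product + offset accumulation
oracle_combine <- function(a, b) {
  prod <- outer(a, b)
  off <- outer(seq_along(a) - 1, seq_along(b) - 1, "+")
  out <- numeric(max(off) + 1)
  for (k in 0:max(off)) out[k + 1] <- sum(prod[off == k])
  out
}

# full-length natural isotopomer pattern of a composition (no truncation)
oracle_natural <- function(comp, abundances = natural_abundances()) {
  out <- 1
  for (el in names(abundances)) {
    n <- if (el %in% names(comp)) comp[[el]] else 0
    if (n > 0) {
      out <- oracle_combine(out, oracle_element_pmf(abundances[[el]], n))
    }
  }
  out
}

# labeled pattern: explicit enumeration of deuterated-site counts at the
# two bracketing integer site numbers, mixed by the fractional part
oracle_labeled <- function(comp, n_eh, p_w,
                           abundances = natural_abundances()) {
  nat <- oracle_natural(comp, abundances)
  shift_mix <- function(n_sites) {
    out <- numeric(length(nat) + n_sites)
    for (d in 0:n_sites) {
      w <- choose(n_sites, d) * p_w^d * (1 - p_w)^(n_sites - d)
      out[d + seq_along(nat)] <- out[d + seq_along(nat)] + w * nat
    }
    out
  }
  lo <- floor(n_eh); hi <- ceiling(n_eh); frac <- n_eh - lo
  lo_v <- shift_mix(lo)
  if (frac == 0) return(lo_v)
  hi_v <- shift_mix(hi)
  length(lo_v) <- length(hi_v)
  lo_v[is.na(lo_v)] <- 0
  (1 - frac) * lo_v + frac * hi_v
}

# exact exponential-rise series
make_series <- function(k, I0, Ipl, times = c(0, 8, 24, 48, 96, 168)) {
  data.frame(time_h = times, I = I0 + (Ipl - I0) * (1 - exp(-k * times)))
}
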