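# Independent oracles used to freeze expected values. These deliberately use
# a different code path from the package internals: the circle is rotated so
# the first cut sits at 0, after which arcs are plain linear intervals and
# membership is a direct comparison.

oracle_free_fraction <- function(cuts, sites, L) {
  cuts <- sort(unique(cuts %% L))
  b <- length(cuts)
  if (b == 0) return(if (length(sites) == 0) 1 else 0)
  cut0 <- (cuts - cuts[1]) %% L
  site0 <- sort((sites - cuts[1]) %% L)
  bounds <- c(sort(cut0), L)
  free <- 0
  for (i in seq_len(b)) {
    s <- bounds[i]; e <- bounds[i + 1]
    if (!any(site0 >= s & site0 < e)) free <- free + (e - s)
  }
  free / L
}

# brute-force Monte-Carlo expectation of the released fraction under uniform
# independent breaks and attachments on the continuous circle
oracle_mc_release <- function(a, b, n_rep, seed) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(i) {
    oracle_free_fraction(stats::runif(b), stats::runif(a), 1)
  }, numeric(1)))
}

# noiseless saturating-exponential series
kinetic_series <- function(f0, A, k, times = c(0, 5, 15, 30, 45, 60)) {
  data.frame(time_min = times,
             released_fraction = f0 + A * (1 - exp(-k * times)))
}

default_genome <- function() circular_genome()
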