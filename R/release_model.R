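# Nucleoid DNA release: the fraction of chromosomal DNA on fragments that
# retain no attachment of either type. Computed exactly for a given fragment
# set, by Monte Carlo over seeded replicates, and by a closed form for
# uniform independent breaks and attachments.

# Fast kernel: total length of attachment-free arcs given sorted cuts and a
# vector of retained attachment coordinates (both types pooled — any contact
# co-precipitates the fragment with the nucleoid).
free_arc_length <- function(cuts, sites, L) {
  b <- length(cuts)
  if (b == 0L) {
    # intact circle: a single species, free only if nothing is attached
    return(if (length(sites) == 0L) L else 0)
  }
  occ <- arc_site_counts(cuts, sites, L)
  if (b == 1L) return(if (occ[1L] == 0L) L else 0)
  d <- diff(cuts)
  wrap <- L - cuts[b] + cuts[1L]
  sum(d[occ[seq_len(b - 1L)] == 0L]) + if (occ[b] == 0L) wrap else 0
}

#' Released (nucleoid-free) DNA fraction of a fragment set
#'
#' The fraction of total DNA mass on fragments that contain no surviving
#' scaffold site and no surviving envelope site. The map must be the
#' post-break map: targeted scenarios destroy the sites they hit, so apply
#' [apply_breaks_to_map()] first.
#'
#' An intact circular species counts as released only if the map holds no
#' attachments at all (a scaffold-free circle behaves like a plasmid in the
#' precipitation assay).
#'
#' @param frags A `fragment_set`.
#' @param map An `attachment_map` (post-break).
#' @return Released fraction in `[0, 1]`.
#' @examples
#' g <- circular_genome(1000, ter_pos = 500)
#' m <- build_attachment_map(g, layout = "explicit", scaffold_sites = c(0, 500))
#' f <- fragments_from_breaks(g, break_set(g, c(100, 400)))
#' released_fraction(f, m)   # 0.3
#' @export
released_fraction <- function(frags, map) {
  stopifnot(inherits(frags, "fragment_set"), inherits(map, "attachment_map"))
  sites <- c(map$scaffold_sites, map$envelope_sites)
  L <- fragment_total_bp(frags)
  if (frags$residual_circle && nrow(frags$arcs) == 0L)
    return(if (length(sites) == 0L) 1 else 0)
  if (nrow(frags$arcs) == 0L) return(0)
  free <- vapply(seq_len(nrow(frags$arcs)), function(i) {
    a <- frags$arcs[i, ]
    if (length(sites) == 0L) return(a$length)
    inside <- if (a$length >= frags$genome$length_bp) rep(TRUE, length(sites))
              else point_in_arc(sites, a$start, a$end)
    if (any(inside)) 0 else a$length
  }, numeric(1))
  # residual (circular/branched) species is attachment-retained unless the
  # map is empty; its mass is never counted as free when sites exist
  free_resid <- if (length(sites) == 0L) frags$residual_length else 0
  (sum(free) + free_resid) / L
}

#' Closed-form expected release under uniform breaks and attachments
#'
#' For `b` cuts and `a` attachments placed independently and uniformly on a
#' circle, the expected attachment-free DNA fraction is
#' \deqn{E[f] = \frac{b(b-1)}{(a+b)(a+b-1)}, \quad b \ge 2,}
#' the probability that both special points flanking a uniformly chosen
#' locus are cuts. Degenerate cases: `b = 1` gives 1 if `a = 0` (the opened
#' circle is free) else 0 (a single linear chromosome still attached);
#' `b = 0` gives 0.
#'
#' The expression is derived for uniform attachment positions; for the
#' equally spaced `loop_rosette` layout it is an approximation and the Monte
#' Carlo path ([mc_expected_release()]) is authoritative.
#'
#' @param a Number of attachment sites (>= 0).
#' @param b Number of breaks (>= 0).
#' @return Expected released fraction.
#' @examples
#' expected_release_closed_form(50, 100)   # ~0.443: the 50-loop prediction
#' expected_release_closed_form(400, 100)  # ~0.0397
#' @export
expected_release_closed_form <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("a and b must be non-negative", call. = FALSE)
  f <- function(a, b) {
    if (b == 0) return(0)
    if (b == 1) return(if (a == 0) 1 else 0)
    b * (b - 1) / ((a + b) * (a + b - 1))
  }
  mapply(f, a, b)
}

#' Monte-Carlo expected release for uniform breaks
#'
#' Simulates `n_replicates` draws of `b` uniform cuts against an attachment
#' configuration and averages the released fraction. `layout = "uniform"`
#' redraws `a` uniform attachment sites each replicate (matching the closed
#' form's assumptions); `layout = "loop_rosette"` holds the equally spaced
#' map fixed and resamples only the cuts.
#'
#' @param a Number of scaffold attachments.
#' @param b Number of breaks per replicate.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param rng_seed Integer seed.
#' @param layout `"uniform"` or `"loop_rosette"`.
#' @param genome A [circular_genome()]; defaults to the 5-Mb frame.
#' @param n_envelope Envelope sites (rosette apexes), default 0.
#' @return List with `mean`, `se` (standard error over replicates), and the
#'   inputs, of class `release_prediction`.
#' @export
mc_expected_release <- function(a, b, n_replicates = 1e4, rng_seed = NULL,
                                layout = c("uniform", "loop_rosette"),
                                genome = circular_genome(), n_envelope = 0) {
  layout <- match.arg(layout)
  stopifnot(a >= 0, b >= 0, n_replicates >= 1)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  L <- genome$length_bp
  fixed_sites <- NULL
  if (layout == "loop_rosette") {
    m <- build_attachment_map(genome, a, n_envelope, layout = "loop_rosette")
    fixed_sites <- c(m$scaffold_sites, m$envelope_sites)
  }
  fr <- vapply(seq_len(n_replicates), function(i) {
    cuts <- if (b > 0) sort.int(sample.int(L, b, replace = TRUE) - 1)
            else numeric(0)
    cuts <- unique(cuts)
    sites <- if (is.null(fixed_sites)) {
      if (a > 0) sample.int(L, a, replace = TRUE) - 1 else numeric(0)
    } else fixed_sites
    free_arc_length(cuts, sites, L) / L
  }, numeric(1))
  structure(list(released_fraction_mean = mean(fr),
                 released_fraction_se = stats::sd(fr) / sqrt(n_replicates),
                 n_replicates = n_replicates,
                 scenario = "random", a = a, b = b, layout = layout),
            class = "release_prediction")
}

#' @export
print.release_prediction <- function(x, ...) {
  cat(sprintf("<release_prediction> %s: f = %.4f +/- %.4f (a=%d, b=%d, %d reps)\n",
              x$scenario, x$released_fraction_mean, x$released_fraction_se,
              x$a, x$b, x$n_replicates))
  invisible(x)
}

#' Predicted release under the three break-placement scenarios
#'
#' Monte-Carlo mean and standard error of the released fraction for random,
#' scaffold-targeted and envelope-targeted breaks against the same nucleoid
#' geometry — the model underlying the three-way discrimination between
#' break-placement hypotheses.
#'
#' For the targeted scenarios, cuts destroy the attachment they hit; when
#' `b` exceeds the available target sites all sites are cut (with a single
#' warning, not one per replicate).
#'
#' @param genome A [circular_genome()].
#' @param a Number of scaffold sites.
#' @param b Number of breaks per replicate.
#' @param n_envelope Number of envelope (apex) sites.
#' @param n_replicates Monte-Carlo replicates per scenario.
#' @param rng_seed Integer seed.
#' @param layout Attachment layout for the random scenario's map
#'   (`"loop_rosette"` default, or `"uniform"` redrawn per replicate).
#' @return Named list of `release_prediction` objects keyed by scenario.
#' @export
scenario_table <- function(genome, a, b, n_envelope = 0, n_replicates = 1e4,
                           rng_seed = NULL,
                           layout = c("loop_rosette", "uniform")) {
  stopifnot(inherits(genome, "circular_genome"), a >= 0, b >= 0)
  layout <- match.arg(layout)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  L <- genome$length_bp
  rosette <- if (a > 0)
    build_attachment_map(genome, a, n_envelope, layout = "loop_rosette")
  else build_attachment_map(genome, 0, 0, layout = "explicit")
  ros_sites <- c(rosette$scaffold_sites, rosette$envelope_sites)

  # random breaks against the chosen attachment layout
  random <- mc_expected_release(a, b, n_replicates,
                                layout = layout, genome = genome,
                                n_envelope = n_envelope)
  random$scenario <- "random"

  # scaffold-targeted: cuts at min(b, a) distinct bases, each destroying its
  # attachment; envelope apexes keep retaining their loops
  scaffold <- if (a == 0) {
    structure(list(released_fraction_mean = NA_real_,
                   released_fraction_se = NA_real_,
                   n_replicates = 0L, scenario = "scaffold_targeted",
                   a = a, b = b, layout = "loop_rosette"),
              class = "release_prediction")
  } else {
    n_cut <- min(b, length(rosette$scaffold_sites))
    if (b > length(rosette$scaffold_sites))
      warning(sprintf("scaffold_targeted: %d cuts requested, %d sites; cutting all",
                      b, length(rosette$scaffold_sites)), call. = FALSE)
    fr <- vapply(seq_len(n_replicates), function(i) {
      ss <- rosette$scaffold_sites
      cuts <- sort.int(ss[sample.int(length(ss), n_cut)])
      sites <- c(setdiff(rosette$scaffold_sites, cuts), rosette$envelope_sites)
      free_arc_length(cuts, sort.int(sites), L) / L
    }, numeric(1))
    structure(list(released_fraction_mean = mean(fr),
                   released_fraction_se = stats::sd(fr) / sqrt(n_replicates),
                   n_replicates = n_replicates, scenario = "scaffold_targeted",
                   a = a, b = b, layout = "loop_rosette"),
              class = "release_prediction")
  }

  # envelope-targeted: cuts at apexes destroy only the envelope contact
  envelope <- if (n_envelope == 0) {
    structure(list(released_fraction_mean = NA_real_,
                   released_fraction_se = NA_real_,
                   n_replicates = 0L, scenario = "envelope_targeted",
                   a = a, b = b, layout = "loop_rosette"),
              class = "release_prediction")
  } else {
    n_cut <- min(b, length(rosette$envelope_sites))
    if (b > length(rosette$envelope_sites))
      warning(sprintf("envelope_targeted: %d cuts requested, %d sites; cutting all",
                      b, length(rosette$envelope_sites)), call. = FALSE)
    fr <- vapply(seq_len(n_replicates), function(i) {
      es <- rosette$envelope_sites
      cuts <- sort.int(es[sample.int(length(es), n_cut)])
      sites <- c(rosette$scaffold_sites,
                 setdiff(rosette$envelope_sites, cuts))
      free_arc_length(cuts, sort.int(sites), L) / L
    }, numeric(1))
    structure(list(released_fraction_mean = mean(fr),
                   released_fraction_se = stats::sd(fr) / sqrt(n_replicates),
                   n_replicates = n_replicates, scenario = "envelope_targeted",
                   a = a, b = b, layout = "loop_rosette"),
              class = "release_prediction")
  }

  list(random = random, scaffold_targeted = scaffold,
       envelope_targeted = envelope)
}
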