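# Break-placement scenarios: random two-ended breaks, breaks targeted at
# scaffold or envelope attachment points, and replication-fork collapse.

#' Random (uniform) two-ended breaks
#'
#' Places `n` cut positions i.i.d. uniformly on the circle, modelling direct,
#' replication-independent double-strand breaks falling in protein-free DNA.
#' Colliding positions are collapsed.
#'
#' @param genome A [circular_genome()].
#' @param n Requested number of breaks (>= 0).
#' @param rng_seed Integer seed.
#' @return A `break_set` with `scenario = "random"`, `endedness = "two_ended"`.
#' @export
random_breaks <- function(genome, n, rng_seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  cuts <- if (n > 0) sample.int(genome$length_bp, n, replace = TRUE) - 1
          else numeric(0)
  break_set(genome, cuts, endedness = "two_ended", scenario = "random")
}

#' Breaks targeted at scaffold attachment sites
#'
#' Cuts are placed exactly at `n` distinct scaffold sites sampled without
#' replacement; a cut at an attachment severs the DNA-protein contact, so the
#' hit site must be removed from the map before release scoring (see
#' [apply_breaks_to_map()]). Requesting more cuts than sites cuts all sites
#' and emits a warning.
#'
#' @inheritParams random_breaks
#' @param map An `attachment_map` with at least one scaffold site.
#' @return A `break_set` with `scenario = "scaffold_targeted"`.
#' @export
scaffold_targeted_breaks <- function(genome, map, n, rng_seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(map, "attachment_map"))
  sites <- map$scaffold_sites
  if (length(sites) == 0L)
    stop("attachment map has no scaffold sites", call. = FALSE)
  targeted_breaks(genome, sites, n, rng_seed, "scaffold_targeted")
}

#' Breaks targeted at envelope attachment sites (loop apexes)
#'
#' Cuts are placed at sampled envelope sites. A cut destroys only the envelope
#' contact it hits; in a `loop_rosette` layout every resulting arc still
#' contains its loop-base scaffold site, so no DNA is released.
#'
#' @inheritParams scaffold_targeted_breaks
#' @return A `break_set` with `scenario = "envelope_targeted"`.
#' @export
envelope_targeted_breaks <- function(genome, map, n, rng_seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(map, "attachment_map"))
  sites <- map$envelope_sites
  if (length(sites) == 0L)
    stop("attachment map has no envelope sites", call. = FALSE)
  targeted_breaks(genome, sites, n, rng_seed, "envelope_targeted")
}

targeted_breaks <- function(genome, sites, n, rng_seed, scenario) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (n > length(sites)) {
    warning(sprintf("%d cuts requested but only %d target sites; cutting all",
                    n, length(sites)), call. = FALSE)
    n <- length(sites)
  }
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  cuts <- if (n > 0) sites[sample.int(length(sites), n)] else numeric(0)
  bs <- break_set(genome, cuts, endedness = "two_ended", scenario = "explicit")
  bs$scenario <- scenario
  bs
}

#' Remove attachment sites destroyed by targeted breaks
#'
#' A scaffold-targeted cut removes the scaffold site it hits; an
#' envelope-targeted cut removes the envelope site. Random and fork-collapse
#' breaks fall in protein-free DNA and destroy nothing.
#'
#' @param map An `attachment_map`.
#' @param breaks A `break_set`.
#' @return The post-break `attachment_map` to use for release scoring.
#' @export
apply_breaks_to_map <- function(map, breaks) {
  stopifnot(inherits(map, "attachment_map"), inherits(breaks, "break_set"))
  if (breaks$scenario == "scaffold_targeted")
    map$scaffold_sites <- setdiff(map$scaffold_sites, breaks$cut_positions)
  else if (breaks$scenario == "envelope_targeted")
    map$envelope_sites <- setdiff(map$envelope_sites, breaks$cut_positions)
  map
}

#' Replication state for the fork-collapse break model
#'
#' A single replication bubble initiated at the origin with both forks having
#' progressed a fraction `fork_progression` of their ori-to-ter path, i.e.
#' forks sit at `ori +/- progression * L/2` (mod L). `collapsed_forks` names
#' the forks broken at template nicks.
#'
#' @param fork_progression Fraction of the chromosome replicated, in (0, 1).
#' @param collapsed_forks Character subset of `c("cw", "ccw")` (clockwise /
#'   counter-clockwise fork).
#' @param n_fork_pairs Number of nested initiation rounds; only the default
#'   single initiation is modelled quantitatively.
#' @return An object of class `rfc_state`.
#' @export
rfc_state <- function(fork_progression, collapsed_forks = c("cw", "ccw"),
                      n_fork_pairs = 1L) {
  if (!is.numeric(fork_progression) || length(fork_progression) != 1L ||
      fork_progression <= 0 || fork_progression >= 1)
    stop("fork_progression must lie strictly in (0, 1)", call. = FALSE)
  collapsed_forks <- unique(as.character(collapsed_forks))
  if (length(collapsed_forks) &&
      !all(collapsed_forks %in% c("cw", "ccw")))
    stop("collapsed_forks must be a subset of c(\"cw\", \"ccw\")",
         call. = FALSE)
  if (n_fork_pairs != 1L)
    warning("only a single initiation (n_fork_pairs = 1) is modelled; ",
            "nested forks are ignored in downstream accounting",
            call. = FALSE)
  structure(list(fork_progression = fork_progression,
                 collapsed_forks = collapsed_forks,
                 n_fork_pairs = as.integer(n_fork_pairs)),
            class = "rfc_state")
}

#' Fork positions of an rfc_state on a genome
#' @param genome A [circular_genome()].
#' @param state An [rfc_state()].
#' @return Named numeric vector with `cw` and `ccw` fork coordinates.
#' @export
fork_positions <- function(genome, state) {
  stopifnot(inherits(genome, "circular_genome"), inherits(state, "rfc_state"))
  L <- genome$length_bp
  d <- state$fork_progression * L / 2
  c(cw = (genome$ori_pos + d) %% L, ccw = (genome$ori_pos - d) %% L)
}

#' One-ended breaks by replication fork collapse
#'
#' Each collapsed fork contributes one cut at the fork coordinate. The
#' resulting `break_set` carries `endedness = "one_ended_rfc"`; use
#' [rfc_fragments()] for the species-level accounting (ori-anchored linear
#' arm vs the ter-containing branched remainder) that the gel/probe model
#' consumes.
#'
#' @param genome A [circular_genome()].
#' @param state An [rfc_state()]; `fork_progression` strictly in (0, 1).
#' @param rng_seed Unused (fork positions are deterministic); kept for
#'   interface uniformity.
#' @return A `break_set` with `scenario = "rfc"`.
#' @export
rfc_breaks <- function(genome, state, rng_seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"), inherits(state, "rfc_state"))
  pos <- fork_positions(genome, state)[state$collapsed_forks]
  break_set(genome, unname(pos), endedness = "one_ended_rfc",
            scenario = "rfc")
}

#' Species produced by replication fork collapse
#'
#' Under a single initiation, the replicated region spans
#' `ori +/- progression * L/2`. A collapsed fork linearizes an ori-anchored
#' daughter arm spanning that replicated interval, while the replication
#' terminus stays on the circular/branched remainder (which piles up in the
#' well under PFGE). With no collapsed forks, the intact theta structure
#' yields no smear species.
#'
#' Mass bookkeeping is normalized to one genome equivalent: the linear arm
#' carries `progression * L` bp and the branched remainder the balance, so
#' the length-conservation invariant holds.
#'
#' @param genome A [circular_genome()].
#' @param state An [rfc_state()].
#' @return A `fragment_set` whose arcs are the ori-anchored linear species
#'   and whose residual is the branched, ter-containing remainder.
#' @export
rfc_fragments <- function(genome, state) {
  stopifnot(inherits(genome, "circular_genome"), inherits(state, "rfc_state"))
  L <- genome$length_bp
  d <- state$fork_progression * L / 2
  if (length(state$collapsed_forks) == 0L) {
    fs <- fragments_from_breaks(genome, break_set(genome, numeric(0)))
    fs$branched <- TRUE
    return(fs)
  }
  s <- (genome$ori_pos - d) %% L
  e <- (genome$ori_pos + d) %% L
  arm_len <- state$fork_progression * L
  arcs <- data.frame(start = s, end = e, length = arm_len,
                     contains_ori = TRUE,
                     contains_ter = point_in_arc(genome$ter_pos, s, e),
                     scaffold_attached = NA, envelope_attached = NA)
  structure(list(arcs = arcs, residual_circle = TRUE, branched = TRUE,
                 residual_length = L - arm_len, genome = genome),
            class = "fragment_set")
}
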