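# In-silico pulsed-field gel: partition of DNA mass into well, compression
# zone and fragmentation smear, plus origin/terminus probe hybridization.

#' Gel model thresholds
#'
#' Size thresholds of the pulsed-field gel readout. Circular and branched
#' species cannot enter the gel and stay in the well; linear species at or
#' above `cz_min` pile up in the compression zone (the "2 Mb" band); shorter
#' linears run as the fragmentation smear. Fragments below `smear_min` are
#' still counted in the smear but flagged sub-smear.
#'
#' @param smear_min Lower bound of the well-resolved smear, bp (default
#'   20 kb, the low end of the fragment-size range).
#' @param cz_min Compression-zone threshold, bp (default 2 Mb).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(smear_min = 2e4, cz_min = 2e6) {
  if (!(smear_min > 0 && smear_min < cz_min))
    stop("need 0 < smear_min < cz_min", call. = FALSE)
  structure(list(smear_min = smear_min, cz_min = cz_min), class = "gel_model")
}

# compartment of each linear arc
arc_compartment <- function(lengths, gel) {
  ifelse(lengths >= gel$cz_min, "cz", "smear")
}

#' Partition a fragment set over gel compartments
#'
#' @param frags A `fragment_set`.
#' @param gel A [gel_model()].
#' @return Object of class `gel_signal`: `well_mass`, `cz_mass`,
#'   `smear_mass`, `sub_smear_mass` (subset of the smear below `smear_min`),
#'   `fragmentation_fraction` = (smear + cz) / total, and a per-species
#'   table with compartments.
#' @examples
#' g <- circular_genome()
#' gel_partition(fragments_from_breaks(g, random_breaks(g, 100, 1)),
#'               gel_model())
#' @export
gel_partition <- function(frags, gel = gel_model()) {
  stopifnot(inherits(frags, "fragment_set"), inherits(gel, "gel_model"))
  total <- fragment_total_bp(frags)
  arcs <- frags$arcs
  comp <- if (nrow(arcs)) arc_compartment(arcs$length, gel) else character(0)
  well <- frags$residual_length
  cz <- sum(arcs$length[comp == "cz"])
  smear <- sum(arcs$length[comp == "smear"])
  sub <- sum(arcs$length[comp == "smear" & arcs$length < gel$smear_min])
  species <- arcs
  if (nrow(species)) species$compartment <- comp
  structure(list(well_mass = well, cz_mass = cz, smear_mass = smear,
                 sub_smear_mass = sub,
                 fragmentation_fraction = (smear + cz) / total,
                 species = species, total_mass = total, gel = gel),
            class = "gel_signal")
}

#' @export
print.gel_signal <- function(x, ...) {
  cat(sprintf(paste0("<gel_signal> well %.3g | CZ %.3g | smear %.3g bp ",
                     "(fragmentation %.3f)\n"),
              x$well_mass, x$cz_mass, x$smear_mass, x$fragmentation_fraction))
  if (!is.null(x$probe_smear))
    cat(sprintf("  probe smear signals: ori %.3g, ter %.3g\n",
                x$probe_smear[["ori"]], x$probe_smear[["ter"]]))
  invisible(x)
}

#' Origin/terminus probe signals per gel compartment
#'
#' Southern-blot logic: a probe lights up every species containing its point
#' coordinate. By default each such species contributes 1 (count-based,
#' matching relative-ratio readouts); `weight = "mass"` weights by species
#' length. The residual circular/branched species sits in the well and
#' carries every locus not on a linear arc.
#'
#' @param frags A `fragment_set`.
#' @param genome A [circular_genome()] providing the probe coordinates.
#' @param gel A [gel_model()].
#' @param weight `"count"` (default) or `"mass"`.
#' @return A `gel_signal` augmented with `probe_smear`, `probe_cz`,
#'   `probe_well` (each a named vector for `ori` and `ter`) and
#'   `smear_ori_ter_ratio` (NA when the ter smear signal is 0).
#' @export
probe_signals <- function(frags, genome, gel = gel_model(),
                          weight = c("count", "mass")) {
  stopifnot(inherits(genome, "circular_genome"))
  weight <- match.arg(weight)
  sig <- gel_partition(frags, gel)
  arcs <- frags$arcs
  w <- function(len) if (weight == "count") rep(1, length(len)) else len
  probe <- function(contains) {
    out <- c(well = 0, cz = 0, smear = 0)
    if (nrow(arcs)) {
      wt <- w(arcs$length)
      out["cz"] <- sum(wt[contains & sig$species$compartment == "cz"])
      out["smear"] <- sum(wt[contains & sig$species$compartment == "smear"])
    }
    out
  }
  ori_on_arcs <- if (nrow(arcs)) arcs$contains_ori else logical(0)
  ter_on_arcs <- if (nrow(arcs)) arcs$contains_ter else logical(0)
  ori <- probe(ori_on_arcs)
  ter <- probe(ter_on_arcs)
  # residual species (well) carries any probe locus not on a linear arc
  if (frags$residual_length > 0) {
    wres <- if (weight == "count") 1 else frags$residual_length
    if (!any(ori_on_arcs)) ori["well"] <- wres
    if (!any(ter_on_arcs)) ter["well"] <- wres
    # RFC: the branched remainder holds ter even though an arm carries ori
    if (frags$branched && any(ori_on_arcs) && !any(ter_on_arcs))
      ter["well"] <- wres
  }
  sig$probe_well <- c(ori = unname(ori["well"]), ter = unname(ter["well"]))
  sig$probe_cz <- c(ori = unname(ori["cz"]), ter = unname(ter["cz"]))
  sig$probe_smear <- c(ori = unname(ori["smear"]), ter = unname(ter["smear"]))
  sig$smear_ori_ter_ratio <-
    if (sig$probe_smear[["ter"]] > 0)
      sig$probe_smear[["ori"]] / sig$probe_smear[["ter"]] else NA_real_
  sig
}

#' Lower-bound DSB count from mean fragment size
#'
#' Random breakage of an `L`-bp circle into pieces of mean size `m` implies
#' `L / m` breaks; with any fragment loss or incomplete resolution the true
#' in-vivo count can only be higher, so the estimate is a lower bound.
#'
#' @param mean_fragment_bp Mean fragment size, bp (0 < size <= genome).
#' @param genome A [circular_genome()].
#' @return Rounded break count.
#' @examples
#' estimate_dsb_count(5e4, circular_genome(5e6))  # 100
#' @export
estimate_dsb_count <- function(mean_fragment_bp, genome = circular_genome()) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!is.numeric(mean_fragment_bp) || mean_fragment_bp <= 0 ||
      mean_fragment_bp > genome$length_bp)
    stop("mean_fragment_bp must lie in (0, length_bp]", call. = FALSE)
  round(genome$length_bp / mean_fragment_bp)
}

#' DNA content per loop for an n-loop nucleoid
#'
#' @param genome A [circular_genome()].
#' @param n_loops Number of loops (>= 1).
#' @return Loop size in bp (`length_bp / n_loops`).
#' @examples
#' loop_size(circular_genome(5e6), 50)   # 100 kb per loop
#' loop_size(circular_genome(5e6), 400)  # 12.5 kb per domain
#' @export
loop_size <- function(genome, n_loops) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!is.numeric(n_loops) || n_loops < 1)
    stop("n_loops must be >= 1", call. = FALSE)
  genome$length_bp / n_loops
}
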