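# Circular-coordinate frame, attachment maps and fragment bookkeeping.
#
# Conventions used throughout the package:
#   * coordinates are 0-based integers in [0, length_bp);
#   * a cut at position p separates bp p-1 from bp p;
#   * fragments are half-open circular intervals [start, end) with wrap-around,
#     so containment is unambiguous and lengths sum exactly to length_bp;
#   * attachments and probes are points, not footprints.

#' Circular genome coordinate frame
#'
#' Defines the coordinate system shared by all simulation and inference
#' functions: a circular chromosome of `length_bp` base pairs with the
#' replication origin and terminus marked as point coordinates. Defaults
#' describe an \emph{E. coli}-sized chromosome (~5 Mb) with ori and ter at
#' diametrically opposite positions.
#'
#' @param length_bp Chromosome length in bp (> 0).
#' @param ori_pos Replication origin coordinate in `[0, length_bp)`.
#' @param ter_pos Replication terminus coordinate in `[0, length_bp)`;
#'   must differ from `ori_pos`.
#' @return An object of class `circular_genome` with fields `length_bp`,
#'   `ori_pos`, `ter_pos`.
#' @examples
#' g <- circular_genome()
#' g$length_bp
#' @export
circular_genome <- function(length_bp = 5e6, ori_pos = 0,
                            ter_pos = floor(length_bp / 2)) {
  length_bp <- as.numeric(length_bp)
  ori_pos <- as.numeric(ori_pos)
  ter_pos <- as.numeric(ter_pos)
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp <= 0)
    stop("length_bp must be a single positive number", call. = FALSE)
  for (p in c(ori_pos, ter_pos))
    if (!is.finite(p) || p < 0 || p >= length_bp)
      stop("ori_pos and ter_pos must lie in [0, length_bp)", call. = FALSE)
  if (ori_pos == ter_pos)
    stop("ori_pos and ter_pos must differ", call. = FALSE)
  structure(list(length_bp = length_bp, ori_pos = ori_pos, ter_pos = ter_pos),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> L = %s bp, ori = %s, ter = %s\n",
              format(x$length_bp, big.mark = ","), x$ori_pos, x$ter_pos))
  invisible(x)
}

#' Build an attachment map (scaffold bases and envelope apexes)
#'
#' Places point attachments of the chromosomal DNA on the circle. Scaffold
#' sites model contacts at the central proteinaceous scaffold (the bases of
#' DNA loops); envelope sites model contacts at the cell envelope (loop
#' apexes, the Bayer-patch sites of growing cells).
#'
#' Layouts:
#' \describe{
#'   \item{`uniform`}{sites placed i.i.d. uniformly on the circle (seeded);}
#'   \item{`loop_rosette`}{`n_scaffold` equally spaced loop bases starting at
#'     coordinate 0, with envelope sites at the apex midpoints of the first
#'     `n_envelope` loops — the classical rosette-of-loops nucleoid cartoon;}
#'   \item{`explicit`}{coordinates supplied directly via `scaffold_sites` /
#'     `envelope_sites`.}
#' }
#'
#' @param genome A [circular_genome()].
#' @param n_scaffold Number of scaffold attachment sites (>= 0).
#' @param n_envelope Number of envelope attachment sites; for `loop_rosette`
#'   must not exceed `n_scaffold`.
#' @param layout One of `"uniform"`, `"loop_rosette"`, `"explicit"`.
#' @param rng_seed Integer seed used by the `uniform` layout.
#' @param scaffold_sites,envelope_sites Explicit coordinates (only for
#'   `layout = "explicit"`).
#' @return An object of class `attachment_map` with sorted, deduplicated
#'   `scaffold_sites` and `envelope_sites` and the `layout` label.
#' @examples
#' g <- circular_genome(1000)
#' build_attachment_map(g, n_scaffold = 4, n_envelope = 4,
#'                      layout = "loop_rosette")
#' @export
build_attachment_map <- function(genome, n_scaffold, n_envelope = 0,
                                 layout = c("loop_rosette", "uniform",
                                            "explicit"),
                                 rng_seed = NULL,
                                 scaffold_sites = NULL,
                                 envelope_sites = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  layout <- match.arg(layout)
  L <- genome$length_bp
  if (layout != "explicit") {
    if (n_scaffold < 0 || n_envelope < 0)
      stop("attachment counts must be non-negative", call. = FALSE)
  }
  if (layout == "loop_rosette") {
    if (n_envelope > n_scaffold)
      stop("loop_rosette requires n_envelope <= n_scaffold", call. = FALSE)
    if (n_scaffold > 0) {
      span <- L / n_scaffold
      scaffold_sites <- floor(span * (seq_len(n_scaffold) - 1))
      # apex = midpoint of each loop [base_i, base_{i+1})
      envelope_sites <- floor(span * (seq_len(n_envelope) - 1) + span / 2)
    } else {
      scaffold_sites <- numeric(0)
      envelope_sites <- numeric(0)
    }
  } else if (layout == "uniform") {
    if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
    scaffold_sites <- if (n_scaffold > 0) sample.int(L, n_scaffold) - 1 else numeric(0)
    envelope_sites <- if (n_envelope > 0) sample.int(L, n_envelope) - 1 else numeric(0)
  } else {
    scaffold_sites <- if (is.null(scaffold_sites)) numeric(0) else as.numeric(scaffold_sites)
    envelope_sites <- if (is.null(envelope_sites)) numeric(0) else as.numeric(envelope_sites)
    if (any(c(scaffold_sites, envelope_sites) < 0) ||
        any(c(scaffold_sites, envelope_sites) >= L))
      stop("explicit sites must lie in [0, length_bp)", call. = FALSE)
  }
  structure(list(scaffold_sites = sort(unique(as.numeric(scaffold_sites))),
                 envelope_sites = sort(unique(as.numeric(envelope_sites))),
                 layout = layout,
                 length_bp = L),
            class = "attachment_map")
}

#' @export
print.attachment_map <- function(x, ...) {
  cat(sprintf("<attachment_map> %d scaffold + %d envelope sites (%s layout)\n",
              length(x$scaffold_sites), length(x$envelope_sites), x$layout))
  invisible(x)
}

#' Construct a break set
#'
#' Low-level constructor; usually produced by the scenario generators in
#' `break_models` ([random_breaks()], [scaffold_targeted_breaks()],
#' [envelope_targeted_breaks()], [rfc_breaks()]). Coinciding cut positions are
#' collapsed: a double-strand break is idempotent at a position.
#'
#' @param genome A [circular_genome()].
#' @param cut_positions Cut coordinates in `[0, length_bp)`.
#' @param endedness `"two_ended"` (direct breaks) or `"one_ended_rfc"`
#'   (replication-fork collapse).
#' @param scenario Scenario label.
#' @return An object of class `break_set`.
#' @export
break_set <- function(genome, cut_positions,
                      endedness = c("two_ended", "one_ended_rfc"),
                      scenario = c("random", "scaffold_targeted",
                                   "envelope_targeted", "rfc", "explicit")) {
  stopifnot(inherits(genome, "circular_genome"))
  endedness <- match.arg(endedness)
  scenario <- match.arg(scenario)
  cut_positions <- as.numeric(cut_positions)
  if (length(cut_positions) &&
      (any(cut_positions < 0) || any(cut_positions >= genome$length_bp)))
    stop("cut positions must lie in [0, length_bp)", call. = FALSE)
  structure(list(cut_positions = sort(unique(cut_positions)),
                 endedness = endedness,
                 scenario = scenario,
                 length_bp = genome$length_bp),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set> %d cuts, %s, scenario = %s\n",
              length(x$cut_positions), x$endedness, x$scenario))
  invisible(x)
}

# is point p inside circular half-open interval [s, e)?  Vectorised over p.
point_in_arc <- function(p, s, e) {
  if (s < e) p >= s & p < e else p >= s | p < e
}

#' Fragments produced by a set of cuts on the circle
#'
#' Cutting a circle at `b >= 1` positions yields exactly `b` half-open arcs
#' that tile the circle; zero cuts leave the intact circular species. Each
#' arc is tagged with whether it contains the origin or terminus point and —
#' if an attachment map is supplied — whether it contains surviving scaffold
#' or envelope attachments.
#'
#' @param genome A [circular_genome()].
#' @param breaks A [break_set()].
#' @param map Optional [build_attachment_map()] result (the post-break map:
#'   targeted scenarios remove destroyed sites first, see
#'   [apply_breaks_to_map()]). Attachment tags are `NA` when absent.
#' @return Object of class `fragment_set`: `arcs` (data.frame with `start`,
#'   `end`, `length`, `contains_ori`, `contains_ter`, `scaffold_attached`,
#'   `envelope_attached`), `residual_circle` flag, `branched` flag (used by
#'   the fork-collapse model) and `residual_length`.
#' @examples
#' g <- circular_genome(100, ori_pos = 0, ter_pos = 50)
#' fragments_from_breaks(g, break_set(g, c(10, 60)))
#' @export
fragments_from_breaks <- function(genome, breaks, map = NULL) {
  stopifnot(inherits(genome, "circular_genome"), inherits(breaks, "break_set"))
  L <- genome$length_bp
  cuts <- breaks$cut_positions
  b <- length(cuts)
  if (b == 0L) {
    arcs <- data.frame(start = numeric(0), end = numeric(0),
                       length = numeric(0), contains_ori = logical(0),
                       contains_ter = logical(0),
                       scaffold_attached = logical(0),
                       envelope_attached = logical(0))
    return(structure(list(arcs = arcs, residual_circle = TRUE,
                          branched = FALSE, residual_length = L,
                          genome = genome),
                     class = "fragment_set"))
  }
  start <- cuts
  end <- c(cuts[-1], cuts[1])            # last arc wraps
  len <- ifelse(end > start, end - start, L - start + end)
  if (b == 1L) len <- L                  # single cut opens the whole circle
  arcs <- data.frame(start = start, end = end, length = len)
  arcs$contains_ori <- mapply(point_in_arc, s = start, e = end,
                              MoreArgs = list(p = genome$ori_pos))
  arcs$contains_ter <- mapply(point_in_arc, s = start, e = end,
                              MoreArgs = list(p = genome$ter_pos))
  if (b == 1L) {
    arcs$contains_ori <- TRUE
    arcs$contains_ter <- TRUE
  }
  if (!is.null(map)) {
    occ <- arc_site_counts(cuts, map$scaffold_sites, L)
    arcs$scaffold_attached <- occ > 0
    occ <- arc_site_counts(cuts, map$envelope_sites, L)
    arcs$envelope_attached <- occ > 0
  } else {
    arcs$scaffold_attached <- NA
    arcs$envelope_attached <- NA
  }
  structure(list(arcs = arcs, residual_circle = FALSE, branched = FALSE,
                 residual_length = 0, genome = genome),
            class = "fragment_set")
}

# Number of sites falling in each of the b arcs defined by sorted cuts.
# Arc i (i < b) is [cuts[i], cuts[i+1]); arc b wraps [cuts[b], cuts[1]).
# Returns an integer vector of length b aligned with fragments_from_breaks().
arc_site_counts <- function(cuts, sites, L) {
  b <- length(cuts)
  if (b == 0L) return(integer(0))
  if (length(sites) == 0L) return(integer(b))
  idx <- findInterval(sites, cuts)       # 0..b; 0 and b both mean the wrap arc
  occ <- tabulate(idx + 1L, nbins = b + 1L)
  counts <- integer(b)
  if (b > 1L) counts[seq_len(b - 1L)] <- occ[2:b]
  counts[b] <- occ[1L] + occ[b + 1L]
  counts
}

#' @export
print.fragment_set <- function(x, ...) {
  if (x$residual_circle)
    cat(sprintf("<fragment_set> intact circular species (%s bp)%s\n",
                format(x$residual_length, big.mark = ","),
                if (x$branched) ", branched" else ""))
  else
    cat(sprintf("<fragment_set> %d linear arcs (total %s bp)%s\n",
                nrow(x$arcs), format(sum(x$arcs$length), big.mark = ","),
                if (x$residual_length > 0)
                  sprintf(" + residual %s bp",
                          format(x$residual_length, big.mark = ",")) else ""))
  invisible(x)
}

#' Total DNA mass of a fragment set (arcs + residual species)
#' @param frags A `fragment_set`.
#' @return Total length in bp; equals the genome length for cut-derived sets.
#' @export
fragment_total_bp <- function(frags) {
  stopifnot(inherits(frags, "fragment_set"))
  sum(frags$arcs$length) + frags$residual_length
}

#' Write / read attachment maps as BED-like text
#'
#' Three-column BED (chrom, start, end with `end = start + 1` for point
#' sites) plus a fourth name column, `"scaffold"` or `"envelope"`.
#'
#' @param map An `attachment_map`.
#' @param path Output (input) file path.
#' @param genome A [circular_genome()] used for validation on read.
#' @return `write_attachment_bed` returns `path` invisibly;
#'   `read_attachment_bed` returns an `attachment_map` with layout
#'   `"explicit"`.
#' @export
write_attachment_bed <- function(map, path) {
  stopifnot(inherits(map, "attachment_map"))
  df <- rbind(
    if (length(map$scaffold_sites))
      data.frame(chrom = "chr", start = map$scaffold_sites,
                 end = map$scaffold_sites + 1, name = "scaffold"),
    if (length(map$envelope_sites))
      data.frame(chrom = "chr", start = map$envelope_sites,
                 end = map$envelope_sites + 1, name = "envelope"))
  if (is.null(df))
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), name = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_attachment_bed
#' @export
read_attachment_bed <- function(path, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  if (file.size(path) == 0)
    return(build_attachment_map(genome, 0, 0, layout = "explicit"))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  if (any(df$end != df$start + 1))
    stop("attachment BED must contain point sites (end == start + 1)",
         call. = FALSE)
  bad <- !df$name %in% c("scaffold", "envelope")
  if (any(bad))
    stop("unknown site type in BED name column: ",
         paste(unique(df$name[bad]), collapse = ", "), call. = FALSE)
  build_attachment_map(genome, layout = "explicit",
                       scaffold_sites = df$start[df$name == "scaffold"],
                       envelope_sites = df$start[df$name == "envelope"])
}
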