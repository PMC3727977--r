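#' Alignment parameters
#'
#' Controls the dynamic-programming alignment of a single Rmap against a
#' reference fragment map. The score is a sum over matched blocks of a
#' squared sizing z-score plus per-cut penalties, so the sizing term has a
#' likelihood interpretation under multiplicative mass noise.
#'
#' @param sizing_cv Relative standard deviation assumed for fragment masses
#'   (sigma of the sizing z-score); the variance scales with the reference
#'   mass, reflecting multiplicative measurement noise.
#' @param miss_penalty Cost per reference cut absorbed inside a block
#'   (missing cut in the molecule).
#' @param extra_penalty Cost per query cut absorbed inside a block (extra
#'   cut in the molecule).
#' @param max_block Maximum consecutive fragments merged on either side of a
#'   block.
#' @param accept_threshold Maximum mean cost per aligned query fragment for
#'   an alignment to be accepted.
#' @param min_aligned_frags Minimum query fragments for alignment to be
#'   attempted.
#' @param refine_z_cap During consensus refinement and
#'   consensus-versus-reference classification the squared sizing z-score of
#'   a block is capped at `refine_z_cap^2`, so a genuine structural mass
#'   change (an insertion can sit 15 sigma from the reference) costs a
#'   bounded amount and is not contorted into spurious merges. The strict
#'   genome-wide aligner never caps.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(sizing_cv = 0.06, miss_penalty = 3.0,
                             extra_penalty = 3.0, max_block = 4L,
                             accept_threshold = 2.0, min_aligned_frags = 8L,
                             refine_z_cap = 4) {
  stopifnot(sizing_cv > 0, miss_penalty > 0, extra_penalty > 0,
            max_block >= 1, accept_threshold > 0, min_aligned_frags >= 1,
            refine_z_cap > 0)
  structure(list(sizing_cv = sizing_cv, miss_penalty = miss_penalty,
                 extra_penalty = extra_penalty, max_block = as.integer(max_block),
                 accept_threshold = accept_threshold,
                 min_aligned_frags = as.integer(min_aligned_frags),
                 refine_z_cap = refine_z_cap),
            class = "alignment_params")
}

#' Cost of matching one block of query fragments against reference fragments
#'
#' `cost = ((q - r) / (sizing_cv * r))^2 + (n_query - 1) * extra_penalty +
#' (n_ref - 1) * miss_penalty`, where `q` and `r` are the block mass sums.
#'
#' @param query_mass_kb,ref_mass_kb Block mass sums in kb (both `> 0`).
#' @param params An [alignment_params()].
#' @param n_query,n_ref Number of fragments merged on each side.
#' @export
block_cost <- function(query_mass_kb, ref_mass_kb, params = alignment_params(),
                       n_query = 1L, n_ref = 1L) {
  if (any(query_mass_kb <= 0) || any(ref_mass_kb <= 0))
    stop("block masses must be positive")
  z <- (query_mass_kb - ref_mass_kb) / (params$sizing_cv * ref_mass_kb)
  z^2 + (n_query - 1) * params$extra_penalty + (n_ref - 1) * params$miss_penalty
}

# bp boundaries of a map's fragments: length(fragments) + 1 positions.
# Window and hypothesis maps carry start_bp/end_bp attributes so their cut
# coordinates stay absolute.
map_boundaries <- function(map) {
  s <- attr(map, "start_bp"); if (is.null(s)) s <- 0
  e <- attr(map, "end_bp")
  if (!is.null(map$cut_coords)) {
    if (is.null(e)) e <- s + round(sum(map$fragments) * 1000)
    c(s, map$cut_coords, e)
  } else {
    if (is.null(e)) return(s + round(c(0, cumsum(map$fragments)) * 1000))
    b <- s + round(c(0, cumsum(map$fragments)) * 1000)
    b[length(b)] <- e
    b
  }
}

as_reference_list <- function(reference) {
  if (inherits(reference, "genome_maps")) return(reference$maps)
  if (inherits(reference, "fragment_map")) {
    out <- list(reference)
    names(out) <- if (is.null(reference$chrom)) reference$map_id else reference$chrom
    return(out)
  }
  stopifnot(is.list(reference), all(vapply(reference, inherits, logical(1),
                                           "fragment_map")))
  reference
}

# Assemble one rmap_alignment record from a DP result.
finish_alignment <- function(res, rm, map, chrom, orientation, params) {
  blocks <- res$blocks
  m <- length(rm$fragments)
  b <- map_boundaries(map)
  oriented <- if (orientation == "+") rm$fragments else rev(rm$fragments)
  rf <- res$ref_first; rl <- res$ref_last
  start <- max(b[rf] - round(oriented[1] * 1000), b[1])
  end <- min(b[rl + 1L] + round(oriented[m] * 1000), b[length(b)])
  n_missing <- sum(blocks[, "ref_end"] - blocks[, "ref_start"])
  n_extra <- sum(blocks[, "q_end"] - blocks[, "q_start"])
  worst <- max(res$block_sizing_cost)
  structure(list(
    molecule_id = rm$molecule_id, chrom = chrom, orientation = orientation,
    blocks = blocks, block_sizing_cost = res$block_sizing_cost,
    total_cost = res$cost, mean_cost = res$cost / m,
    forgiven_cost = (res$cost - worst) / m,
    n_missing_cuts = n_missing, n_extra_cuts = n_extra,
    ref_first = rf, ref_last = rl,
    ref_span_bp = c(start = start, end = end),
    midpoint_bp = floor((start + end) / 2),
    n_query_frags = m, oriented_fragments = oriented,
    source_label = rm$source_label, status = "aligned"),
    class = "rmap_alignment")
}

#' Align one Rmap against a reference
#'
#' Dynamic program over fragment blocks, both orientations, all chromosomes.
#' The two terminal query fragments are unscored (molecule ends are random
#' shear points). The best placement is accepted iff its mean cost per
#' query fragment is at most `accept_threshold`; ties are broken toward
#' forward orientation, earlier chromosome, leftmost start.
#'
#' @param rm An [rmap()].
#' @param reference A [genome_maps()], a single [fragment_map()], or a named
#'   list of fragment maps.
#' @param params An [alignment_params()].
#' @param forgive_worst_block When `TRUE`, acceptance is judged on the total
#'   cost minus the largest single block sizing term, so one structural
#'   difference (e.g. an insertion carried by the molecule) does not reject
#'   an otherwise concordant placement. Used when recruiting molecules onto
#'   evolving consensus maps.
#' @param z2_cap Cap on the squared sizing z-score per block (winsorized
#'   sizing); `Inf` for the strict genome-wide aligner, `refine_z_cap^2`
#'   during consensus refinement and classification.
#' @return An object of class `rmap_alignment` with `status` `"aligned"`,
#'   or a stub with `status` `"rejected_short"` / `"rejected_score"`.
#' @export
align_rmap <- function(rm, reference, params = alignment_params(),
                       forgive_worst_block = FALSE, z2_cap = Inf) {
  maps <- as_reference_list(reference)
  m <- length(rm$fragments)
  if (m < max(params$min_aligned_frags, 3L))
    return(structure(list(molecule_id = rm$molecule_id,
                          status = "rejected_short"),
                     class = "rmap_alignment"))
  interior <- rm$fragments[2:(m - 1L)]
  best <- NULL; best_key <- NULL
  for (ci in seq_along(maps)) {
    map <- maps[[ci]]
    for (orientation in c("+", "-")) {
      qi <- if (orientation == "+") interior else rev(interior)
      res <- .dp_fit_align(map$fragments, qi, params$sizing_cv,
                           params$extra_penalty, params$miss_penalty,
                           params$max_block, z2_cap)
      if (!is.finite(res$cost)) next
      aln <- finish_alignment(res, rm, map, names(maps)[ci], orientation, params)
      key <- c(aln$total_cost, orientation != "+", ci, aln$ref_span_bp["start"])
      if (is.null(best) || compare_keys(key, best_key) < 0) {
        best <- aln; best_key <- key
      }
    }
  }
  if (is.null(best))
    return(structure(list(molecule_id = rm$molecule_id,
                          status = "rejected_score"),
                     class = "rmap_alignment"))
  stat <- if (forgive_worst_block) best$forgiven_cost else best$mean_cost
  if (stat > params$accept_threshold) {
    best$status <- "rejected_score"
  }
  best
}

compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' Align a batch of Rmaps
#'
#' @param rmaps List of [rmap()] objects.
#' @inheritParams align_rmap
#' @return A list with `table` (one row per molecule: `molecule_id, chrom,
#'   start, end, orientation, n_blocks, cost, midpoint, source_label,
#'   status`) and `alignments` (named list of accepted `rmap_alignment`
#'   objects).
#' @export
align_batch <- function(rmaps, reference, params = alignment_params(),
                        forgive_worst_block = FALSE, z2_cap = Inf) {
  maps <- as_reference_list(reference)
  n <- length(rmaps)
  rows <- vector("list", n)
  alns <- vector("list", n)
  ids <- vapply(rmaps, function(r) r$molecule_id, character(1))
  # batch the DP per chromosome: collect eligible interiors once
  sizes <- vapply(rmaps, function(r) length(r$fragments), integer(1))
  eligible <- which(sizes >= max(params$min_aligned_frags, 3L))
  interiors <- lapply(rmaps[eligible],
                      function(r) r$fragments[2:(length(r$fragments) - 1L)])
  per_chrom <- lapply(seq_along(maps), function(ci)
    .dp_align_many(interiors, maps[[ci]]$fragments, params$sizing_cv,
                   params$extra_penalty, params$miss_penalty, params$max_block,
                   z2_cap))
  for (k in seq_along(eligible)) {
    i <- eligible[k]
    best <- NULL; best_key <- NULL
    for (ci in seq_along(maps)) {
      res <- per_chrom[[ci]][[k]]
      if (!is.finite(res$cost)) next
      aln <- finish_alignment(res, rmaps[[i]], maps[[ci]], names(maps)[ci],
                              res$orientation, params)
      key <- c(aln$total_cost, res$orientation != "+", ci,
               aln$ref_span_bp["start"])
      if (is.null(best) || compare_keys(key, best_key) < 0) {
        best <- aln; best_key <- key
      }
    }
    if (is.null(best)) {
      alns[[i]] <- structure(list(molecule_id = ids[i],
                                  status = "rejected_score"),
                             class = "rmap_alignment")
    } else {
      stat <- if (forgive_worst_block) best$forgiven_cost else best$mean_cost
      if (stat > params$accept_threshold) best$status <- "rejected_score"
      alns[[i]] <- best
    }
  }
  for (i in setdiff(seq_len(n), eligible))
    alns[[i]] <- structure(list(molecule_id = ids[i],
                                status = "rejected_short"),
                           class = "rmap_alignment")
  tab <- alignment_table(alns, rmaps)
  accepted <- alns[vapply(alns, function(a) a$status == "aligned", logical(1))]
  names(accepted) <- vapply(accepted, function(a) a$molecule_id, character(1))
  list(table = tab, alignments = accepted)
}

alignment_table <- function(alns, rmaps = NULL) {
  # location fields are filled for the best placement even when it was
  # rejected on score -- `status` remains authoritative
  get <- function(a, field, default) if (!is.null(a[[field]])) a[[field]] else default
  data.frame(
    molecule_id = vapply(alns, function(a) a$molecule_id, character(1)),
    chrom = vapply(alns, get, character(1), "chrom", NA_character_),
    start = vapply(alns, function(a)
      if (!is.null(a$ref_span_bp)) unname(a$ref_span_bp["start"]) else NA_real_,
      numeric(1)),
    end = vapply(alns, function(a)
      if (!is.null(a$ref_span_bp)) unname(a$ref_span_bp["end"]) else NA_real_,
      numeric(1)),
    orientation = vapply(alns, get, character(1), "orientation", NA_character_),
    n_blocks = vapply(alns, function(a)
      if (!is.null(a$blocks)) nrow(a$blocks) else NA_integer_, integer(1)),
    cost = vapply(alns, get, numeric(1), "total_cost", NA_real_),
    midpoint = vapply(alns, get, numeric(1), "midpoint_bp", NA_real_),
    source_label = if (is.null(rmaps))
      vapply(alns, function(a) a$source_label %||% ".", character(1))
    else vapply(rmaps, function(r) r$source_label, character(1)),
    status = vapply(alns, function(a) a$status, character(1)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment table to TSV
#' @param table Data frame from [align_batch()].
#' @param path Output path.
#' @export
write_alignment_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
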