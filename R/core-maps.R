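#' Ordered restriction fragment map
#'
#' The universal currency of the pipeline: an ordered sequence of restriction
#' fragment masses (kb) for one contiguous piece of DNA, optionally with the
#' base-pair coordinates of the cut sites separating the fragments.
#'
#' @param map_id Character scalar identifier.
#' @param fragments Numeric vector of fragment masses in kb; all `> 0`.
#'   Masses are rounded to 0.001 kb.
#' @param chrom Optional chromosome name.
#' @param cut_coords Optional integer vector of 0-based bp cut coordinates
#'   (cuts fall *between* bases); length must be `length(fragments) - 1`
#'   and strictly increasing.
#' @param origin One of `"reference"`, `"consensus"`, `"hypothesis"`,
#'   `"molecule"`.
#' @return An object of class `fragment_map`.
#' @export
fragment_map <- function(map_id, fragments, chrom = NULL, cut_coords = NULL,
                         origin = c("reference", "consensus", "hypothesis",
                                    "molecule")) {
  origin <- match.arg(origin)
  fragments <- round_mass(as.numeric(fragments))
  if (length(fragments) < 1L) stop("fragment_map needs >= 1 fragment")
  if (any(!is.finite(fragments)) || any(fragments <= 0))
    stop("all fragment masses must be positive and finite")
  if (!is.null(cut_coords)) {
    cut_coords <- as.numeric(cut_coords)
    if (length(cut_coords) != length(fragments) - 1L)
      stop("need length(fragments) - 1 cut coordinates")
    if (length(cut_coords) > 1L && any(diff(cut_coords) <= 0))
      stop("cut_coords must be strictly increasing")
  }
  structure(
    list(map_id = as.character(map_id), chrom = chrom,
         fragments = fragments, cut_coords = cut_coords, origin = origin),
    class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map %s> %s, %d fragments, %.3f kb total (%s)\n",
              x$map_id, if (is.null(x$chrom)) "." else x$chrom,
              length(x$fragments), sum(x$fragments), x$origin))
  invisible(x)
}

#' Single-molecule Rmap
#'
#' One molecule's ordered restriction map plus its source label (e.g. the
#' tumor slice it was measured from) and, for simulated molecules, the
#' ground-truth origin.
#'
#' @param molecule_id Character scalar.
#' @param fragments Numeric vector of masses in kb, all `> 0`.
#' @param source_label Character scalar, `"."` when unknown.
#' @param truth Optional list with `true_chrom`, `true_start_bp`,
#'   `true_orientation`; present only for simulated molecules.
#' @return An object of class `rmap`.
#' @export
rmap <- function(molecule_id, fragments, source_label = ".", truth = NULL) {
  fragments <- round_mass(as.numeric(fragments))
  if (length(fragments) < 1L) stop("rmap needs >= 1 fragment")
  if (any(!is.finite(fragments)) || any(fragments <= 0))
    stop("all fragment masses must be positive and finite")
  structure(
    list(molecule_id = as.character(molecule_id), fragments = fragments,
         source_label = as.character(source_label), truth = truth),
    class = "rmap")
}

#' @export
print.rmap <- function(x, ...) {
  cat(sprintf("<rmap %s> %d fragments, %.3f kb (source %s)\n",
              x$molecule_id, length(x$fragments), sum(x$fragments),
              x$source_label))
  invisible(x)
}

#' Genome-wide set of reference fragment maps
#'
#' @param maps Named list of [fragment_map()] objects, one per chromosome.
#' @param chrom_lengths_bp Named numeric vector of chromosome spans in bp.
#'   Defaults to 1000 times each map's total mass.
#' @return An object of class `genome_maps`.
#' @export
genome_maps <- function(maps, chrom_lengths_bp = NULL) {
  if (is.null(names(maps)) || anyDuplicated(names(maps)))
    stop("maps must be a uniquely named list (one entry per chromosome)")
  if (is.null(chrom_lengths_bp))
    chrom_lengths_bp <- vapply(maps, function(m) round(sum(m$fragments) * 1000),
                               numeric(1))
  stopifnot(all(names(maps) %in% names(chrom_lengths_bp)))
  structure(
    list(maps = maps, chrom_lengths_bp = chrom_lengths_bp[names(maps)],
         total_length_bp = sum(chrom_lengths_bp[names(maps)])),
    class = "genome_maps")
}

#' @export
print.genome_maps <- function(x, ...) {
  cat(sprintf("<genome_maps> %d chromosome(s), %.2f Mb, %d fragments\n",
              length(x$maps), x$total_length_bp / 1e6,
              sum(vapply(x$maps, function(m) length(m$fragments), integer(1)))))
  invisible(x)
}

#' Restriction enzyme recognition specification
#'
#' Default is SwaI: recognition `ATTTAAAT`, blunt cut between positions 4
#' and 5 of the site.
#'
#' @param site Recognition sequence (fixed-length, over ACGT).
#' @param cut_offset Bases 5' of the cut within the site (cut falls after
#'   this many bases of the recognition sequence).
#' @export
enzyme_spec <- function(site = "ATTTAAAT", cut_offset = 4L) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) stop("recognition site must be over ACGT")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site")
  list(site = site, cut_offset = cut_offset)
}

#' In-silico digestion of a DNA sequence
#'
#' Locates every occurrence of the recognition site and returns the ordered
#' fragment map between successive cut positions, including the two terminal
#' fragments. Windows containing `N` never match, so assembly gaps cannot
#' create phantom cuts.
#'
#' @param sequence A character scalar or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param enzyme An [enzyme_spec()].
#' @param map_id,chrom Identifiers for the returned map.
#' @return A [fragment_map()] with `cut_coords` populated (0-based bp).
#' @export
in_silico_digest <- function(sequence, enzyme = enzyme_spec(),
                             map_id = "ref", chrom = NULL) {
  if (is.character(sequence)) {
    if (!nzchar(sequence)) stop("empty sequence")
    sequence <- Biostrings::DNAString(sequence)
  }
  L <- length(sequence)
  if (L == 0L) stop("empty sequence")
  cuts <- numeric(0)
  if (L >= nchar(enzyme$site)) {
    m <- Biostrings::matchPattern(enzyme$site, sequence, fixed = TRUE)
    if (length(m) > 0L)
      cuts <- BiocGenerics::start(m) - 1L + enzyme$cut_offset
  }
  cuts <- cuts[cuts > 0 & cuts < L]
  frags <- diff(c(0, cuts, L)) / 1000
  fragment_map(map_id, frags, chrom = chrom,
               cut_coords = if (length(cuts)) cuts else NULL,
               origin = "reference")
}

#' Digest every chromosome of a genome
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @inheritParams in_silico_digest
#' @return A [genome_maps()].
#' @export
digest_genome <- function(seqs, enzyme = enzyme_spec()) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named by chromosome")
  maps <- lapply(names(seqs), function(ch)
    in_silico_digest(seqs[[ch]], enzyme, map_id = ch, chrom = ch))
  names(maps) <- names(seqs)
  genome_maps(maps, chrom_lengths_bp = setNames(Biostrings::width(seqs),
                                                names(seqs)))
}

#' Merge fragments below the observable size limit
#'
#' Fragments smaller than `min_kb` (default 0.4 kb) are merged into their
#' left neighbor; the leftmost fragment, having no left neighbor, merges
#' right. Total mass is conserved exactly and the operation is idempotent.
#'
#' @param map A [fragment_map()].
#' @param min_kb Minimum retained fragment mass in kb.
#' @return A [fragment_map()] with no fragment below `min_kb` (unless the
#'   whole map sums below `min_kb`).
#' @export
merge_small_fragments <- function(map, min_kb = 0.4) {
  stopifnot(inherits(map, "fragment_map"), min_kb > 0)
  f <- map$fragments
  cc <- map$cut_coords
  # one left-to-right pass: small fragments accumulate into the previous one
  out <- numeric(0); out_cc <- numeric(0)
  for (i in seq_along(f)) {
    if (length(out) && f[i] < min_kb) {
      out[length(out)] <- out[length(out)] + f[i]
    } else {
      out <- c(out, f[i])
      if (length(out) > 1L && !is.null(cc)) out_cc <- c(out_cc, cc[i - 1L])
    }
  }
  # leading small fragment merges into its right neighbor
  while (length(out) > 1L && out[1L] < min_kb) {
    out[2L] <- out[1L] + out[2L]
    out <- out[-1L]
    if (length(out_cc)) out_cc <- out_cc[-1L]
  }
  fragment_map(map$map_id, out, chrom = map$chrom,
               cut_coords = if (length(out_cc)) out_cc else NULL,
               origin = map$origin)
}

#' @rdname merge_small_fragments
#' @param genome A [genome_maps()].
#' @export
merge_small_fragments_genome <- function(genome, min_kb = 0.4) {
  stopifnot(inherits(genome, "genome_maps"))
  genome_maps(lapply(genome$maps, merge_small_fragments, min_kb = min_kb),
              chrom_lengths_bp = genome$chrom_lengths_bp)
}

# ---- on-disk map format -----------------------------------------------------

MAP_TSV_HEADER <- c(
  "# rmapforge map v1",
  "# coords: 0-based half-open bp; masses: kb, 3 decimals",
  "# map_id\tchrom\tn_frags\tfragments_kb\tsource_label")

#' Read and write collections of maps
#'
#' One tab-separated dialect serves molecules and consensus/reference maps
#' alike: comment lines start with `#`; each data line is
#' `map_id TAB chrom-or-. TAB n_frags TAB comma-separated-masses TAB
#' source_label-or-.`. Records with chromosome `.` are returned as [rmap()]
#' molecules (the source label carries the slice id); records with a
#' chromosome are returned as [fragment_map()]s whose source field carries
#' the origin.
#'
#' @param path File path.
#' @return `read_maps()`: a list of [rmap()] / [fragment_map()] objects.
#' @export
read_maps <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("no map records in ", path)
    return(list())
  }
  idx <- which(keep)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 5L)
      stop(sprintf("line %d of %s: expected 5 tab-separated fields, got %d",
                   i, path, length(fields)))
    masses <- suppressWarnings(as.numeric(strsplit(fields[4L], ",")[[1L]]))
    if (anyNA(masses) || any(masses <= 0))
      stop(sprintf("line %d of %s: non-positive or unparsable fragment mass",
                   i, path))
    if (length(masses) != as.integer(fields[3L]))
      stop(sprintf("line %d of %s: n_frags=%s but %d masses given",
                   i, path, fields[3L], length(masses)))
    if (fields[2L] == ".") {
      out[[k]] <- rmap(fields[1L], masses, source_label = fields[5L])
    } else {
      origin <- if (fields[5L] %in% c("reference", "consensus", "hypothesis"))
        fields[5L] else "reference"
      out[[k]] <- fragment_map(fields[1L], masses, chrom = fields[2L],
                               origin = origin)
    }
  }
  out
}

#' @rdname read_maps
#' @param maps A list of [rmap()] / [fragment_map()] objects.
#' @export
write_maps <- function(maps, path) {
  if (inherits(maps, c("rmap", "fragment_map"))) maps <- list(maps)
  lines <- vapply(maps, function(m) {
    masses <- paste(sprintf("%.3f", m$fragments), collapse = ",")
    if (inherits(m, "rmap")) {
      paste(m$molecule_id, ".", length(m$fragments), masses, m$source_label,
            sep = "\t")
    } else {
      paste(m$map_id, if (is.null(m$chrom)) "." else m$chrom,
            length(m$fragments), masses, m$origin, sep = "\t")
    }
  }, character(1))
  writeLines(c(MAP_TSV_HEADER, lines), path)
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings kept so every pipeline stage shares one
#' entry point for sequence IO.
#'
#' @param path File path.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs A named [Biostrings::DNAStringSet] or character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED4+ interval file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention GenomicRanges uses.
#'
#' @param path BED file path (>= 4 columns: chrom, start, end, name).
#' @return A [GenomicRanges::GRanges] with a `name` metadata column.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (!length(keep)) return(GenomicRanges::GRanges(name = character(0)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 4L)
      stop(sprintf("line %d of %s: BED4+ needs >= 4 columns", keep[k], path))
    s <- suppressWarnings(as.numeric(p[2L])); e <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(s) || is.na(e) || e < s)
      stop(sprintf("line %d of %s: bad interval [%s, %s)", keep[k], path,
                   p[2L], p[3L]))
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start <- as.numeric(vapply(parts, `[`, character(1), 2L))
  end   <- as.numeric(vapply(parts, `[`, character(1), 3L))
  name  <- vapply(parts, `[`, character(1), 4L)
  score <- vapply(parts, function(p) if (length(p) >= 5L) p[5L] else NA_character_,
                  character(1))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               name = name)
  if (!all(is.na(score))) gr$score <- suppressWarnings(as.numeric(score))
  gr
}

#' @rdname read_bed
#' @param gr A `GRanges` with a `name` column (and optionally `score`).
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(BiocGenerics::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(BiocGenerics::end(gr), scientific = FALSE, trim = TRUE),
    name = if (!is.null(gr$name)) gr$name else ".",
    stringsAsFactors = FALSE)
  if (!is.null(gr$score)) df$score <- gr$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
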