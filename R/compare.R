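#' Type-specific intersection windows
#'
#' OSA-versus-panel matching expands intervals by a class-specific window
#' before testing for >= 1 bp overlap: 100 bp for MCs, 4200 bp for ECs and
#' 0 bp for INS/DEL/OTHER against optical-map panels; 100 bp (MC) / 3000 bp
#' (EC) against SNP panels. External (sequence-derived) variant sets are
#' routed by size: events smaller than 3 kb are compared to ECs and MCs
#' (small indels below optical resolution surface as cut differences),
#' events of 3 kb and larger to INS/DEL/OTHER with a 0 bp window.
#'
#' @param om_windows Named numeric vector of expansion windows (bp) per OSA
#'   class for optical-map panels.
#' @param snp_windows Windows for SNP panels (cut classes only).
#' @param external_size_partition_bp Size (bp) separating the two routing
#'   regimes for external panels.
#' @export
intersection_rules <- function(om_windows = c(MC = 100, EC = 4200, INS = 0,
                                              DEL = 0, OTHER = 0),
                               snp_windows = c(MC = 100, EC = 3000),
                               external_size_partition_bp = 3000) {
  stopifnot(all(om_windows >= 0), all(snp_windows >= 0),
            external_size_partition_bp >= 0)
  structure(list(om_windows = as.list(om_windows),
                 snp_windows = as.list(snp_windows),
                 external_size_partition_bp = external_size_partition_bp),
            class = "intersection_rules")
}

osa_granges <- function(osas) {
  # cut-class OSAs are 1 bp intervals at the inferred cut coordinate
  start <- ifelse(osas$class %in% c("EC", "MC") & !is.na(osas$cut_bp),
                  osas$cut_bp, osas$start)
  end <- ifelse(osas$class %in% c("EC", "MC") & !is.na(osas$cut_bp),
                osas$cut_bp + 1, osas$end)
  GenomicRanges::GRanges(osas$chrom,
                         IRanges::IRanges(start + 1, pmax(end, start + 1)),
                         class = osas$class)
}

expand_gr <- function(gr, w) {
  if (w <= 0) return(gr)
  GenomicRanges::trim(suppressWarnings(gr + w))
}

#' Intersect OSA calls with a typed variant panel
#'
#' Only variants of corresponding type are compared: for optical-map panels
#' the classes must match; for SNP panels only cut classes are compared;
#' for external panels events are routed by the 3 kb size partition. The
#' OSA interval is expanded symmetrically by the class window and a match
#' requires >= 1 bp overlap.
#'
#' @param osas OSA data frame (from [call_genome()]; needs `class, chrom,
#'   start, end`, optionally `cut_bp`).
#' @param panel A `GRanges` with a `name` column: the OSA class for
#'   `"om"` panels, anything for `"snp"`, the class or size for
#'   `"external"` panels (size taken from interval width).
#' @param panel_type `"om"`, `"snp"` or `"external"`.
#' @param rules An [intersection_rules()].
#' @return Data frame: one row per OSA with `matched` (logical) and
#'   `nearest_distance_bp` (NA when the panel has no comparable record).
#' @export
intersect_panel <- function(osas, panel, panel_type = c("om", "snp",
                                                        "external"),
                            rules = intersection_rules()) {
  panel_type <- match.arg(panel_type)
  n <- nrow(osas)
  matched <- logical(n); nearest <- rep(NA_real_, n)
  if (n == 0L)
    return(data.frame(matched = matched, nearest_distance_bp = nearest))
  gr <- osa_granges(osas)
  if (panel_type == "om") {
    bad <- setdiff(unique(panel$name), c("EC", "MC", "INS", "DEL", "OTHER"))
    if (length(bad)) stop("unknown OSA class in panel: ",
                          paste(bad, collapse = ", "))
  }
  for (i in seq_len(n)) {
    cls <- osas$class[i]
    if (panel_type == "om") {
      cmp <- panel[panel$name == cls]
      w <- rules$om_windows[[cls]] %||% 0
    } else if (panel_type == "snp") {
      if (!cls %in% names(rules$snp_windows)) next
      cmp <- panel
      w <- rules$snp_windows[[cls]]
    } else {
      sizes <- BiocGenerics::width(panel)
      small <- sizes < rules$external_size_partition_bp
      if (cls %in% c("EC", "MC")) {
        cmp <- panel[small]
        w <- rules$snp_windows[[cls]] %||% 0
      } else {
        cmp <- panel[!small]
        w <- 0
      }
    }
    if (!length(cmp)) next
    g <- expand_gr(gr[i], w)
    hits <- GenomicRanges::countOverlaps(g, cmp, minoverlap = 1L) > 0
    matched[i] <- as.logical(hits)
    d <- GenomicRanges::distanceToNearest(gr[i], cmp)
    if (length(d)) nearest[i] <- S4Vectors::mcols(d)$distance
  }
  data.frame(matched = matched, nearest_distance_bp = nearest)
}

#' Filter somatic candidates against panels of known variation
#'
#' An OSA is a somatic candidate iff it matches in none of the supplied
#' panels; everything else is removed, with a per-panel tally. Candidates
#' and removed calls partition the input exactly.
#'
#' @param osas OSA data frame.
#' @param panels Named list; each element a list with `granges` (the panel)
#'   and `type` (`"om"`, `"snp"`, `"external"`), or a bare `GRanges`
#'   (treated as type `"om"`).
#' @param rules An [intersection_rules()].
#' @return List with `candidates`, `removed` (both data frames with a
#'   `matched_panels` column), and `tally` (named count of matches per
#'   panel).
#' @export
filter_somatic <- function(osas, panels, rules = intersection_rules()) {
  if (length(panels) == 0L) {
    warning("no panels supplied; every call is a candidate")
    osas$matched_panels <- ""
    return(list(candidates = osas, removed = osas[0, , drop = FALSE],
                tally = integer(0)))
  }
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("panels must be named")
  match_mat <- matrix(FALSE, nrow(osas), length(panels),
                      dimnames = list(NULL, names(panels)))
  for (p in names(panels)) {
    pn <- panels[[p]]
    if (methods::is(pn, "GRanges")) pn <- list(granges = pn, type = "om")
    match_mat[, p] <- intersect_panel(osas, pn$granges, pn$type, rules)$matched
  }
  any_match <- rowSums(match_mat) > 0
  osas$matched_panels <- apply(match_mat, 1L, function(z)
    paste(names(panels)[z], collapse = ","))
  list(candidates = osas[!any_match, , drop = FALSE],
       removed = osas[any_match, , drop = FALSE],
       tally = colSums(match_mat))
}

#' Annotate OSA calls with overlapping genes
#'
#' Half-open interval overlap of >= 1 bp; every overlapping gene is
#' reported.
#'
#' @param osas OSA data frame.
#' @param genes A `GRanges` with gene names in `name` (e.g. from
#'   [read_bed()]).
#' @return `osas` with a `genes` column (comma-separated, `""` when none).
#' @export
annotate_genes <- function(osas, genes) {
  if (!nrow(osas)) { osas$genes <- character(0); return(osas) }
  gr <- osa_granges(osas)
  hits <- GenomicRanges::findOverlaps(gr, genes, minoverlap = 1L)
  per <- split(genes$name[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits))
  osas$genes <- ""
  osas$genes[as.integer(names(per))] <-
    vapply(per, function(g) paste(unique(g), collapse = ","), character(1))
  osas
}
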