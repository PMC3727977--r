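#' Thresholds for optical structural alteration calling
#'
#' Indels are called when a consensus fragment deviates from its reference
#' counterpart by at least 13% of the reference mass, with a 4.5 kb floor;
#' reference fragments below 0.4 kb are merged before comparison; runs of
#' two or more differences within three consecutive reference fragments
#' collapse into a single complex ("OTHER") event.
#'
#' @param indel_rel Relative deviation threshold (fraction of reference
#'   fragment mass).
#' @param indel_min_kb Absolute deviation floor, kb.
#' @param merge_min_kb Reference fragments below this are merged first.
#' @param other_window_frags Span (consecutive reference fragments) within
#'   which multiple differences collapse into one OTHER event.
#' @param alpha Family-wise significance level for support scoring.
#' @param cut_match_tol_bp A novel consensus cut within this distance (in
#'   mapped reference coordinates) of an unmatched reference cut is
#'   identified with it rather than reported as an EC/MC pair.
#' @param min_observable_kb Cut differences flanked by a reference fragment
#'   below this mass are not called: such fragments are desorbed from the
#'   mapping surface in most molecules, so their cuts carry no evidence.
#' @export
call_thresholds <- function(indel_rel = 0.13, indel_min_kb = 4.5,
                            merge_min_kb = 0.4, other_window_frags = 3L,
                            alpha = 0.05, cut_match_tol_bp = 2500,
                            min_observable_kb = 0.8) {
  stopifnot(indel_rel > 0, indel_min_kb > 0, merge_min_kb > 0,
            other_window_frags >= 1, alpha > 0, alpha <= 1,
            cut_match_tol_bp >= 0, min_observable_kb >= 0)
  structure(list(indel_rel = indel_rel, indel_min_kb = indel_min_kb,
                 merge_min_kb = merge_min_kb,
                 other_window_frags = as.integer(other_window_frags),
                 alpha = alpha, cut_match_tol_bp = cut_match_tol_bp,
                 min_observable_kb = min_observable_kb),
            class = "call_thresholds")
}

# minimal calling deviation for a reference fragment of r kb, quantized to
# the 0.001 kb mass grid
indel_min_deviation <- function(r, thresholds) {
  round_mass(pmax(thresholds$indel_rel * r, thresholds$indel_min_kb))
}

#' Classify consensus-versus-reference differences into OSA calls
#'
#' Aligns the consensus map to the (pre-merged) reference window map and
#' walks the matched blocks: an unmatched reference interior cut is a
#' missing cut (MC); an unmatched consensus interior cut is an extra cut
#' (EC); a one-to-one block whose mass deviation reaches
#' `max(indel_rel * r, indel_min_kb)` is an insertion (INS, consensus
#' larger) or deletion (DEL, smaller). Sub-threshold indels are never
#' emitted; they surface only as cut differences. Any run of two or more
#' differences within `other_window_frags` consecutive reference fragments
#' collapses into one OTHER call spanning the run.
#'
#' @param consensus A consensus [fragment_map()] (from [assemble_window()]).
#' @param reference The reference window [fragment_map()] (absolute cut
#'   coordinates). Merged at `merge_min_kb` internally.
#' @param thresholds A [call_thresholds()].
#' @param aln_params An [alignment_params()].
#' @param collapse When `FALSE`, primitive differences are returned without
#'   complex-event aggregation (used by [call_genome()], which scores
#'   primitives before aggregating).
#' @return Data frame of calls: `class, chrom, start, end, size_delta_kb,
#'   ref_frag_lo, ref_frag_hi, cut_bp, consensus_frag, n_diffs`.
#' @export
classify_differences <- function(consensus, reference,
                                 thresholds = call_thresholds(),
                                 aln_params = alignment_params(),
                                 collapse = TRUE) {
  if (!is.null(attr(consensus, "cut_seed_id")))
    return(classify_by_provenance(consensus, reference, thresholds,
                                  collapse = collapse))
  ref <- merge_small_fragments(reference, thresholds$merge_min_kb)
  attr(ref, "start_bp") <- attr(reference, "start_bp") %||% 0
  attr(ref, "end_bp") <- attr(reference, "end_bp")
  rb <- map_boundaries(ref)
  chrom <- reference$chrom %||% reference$map_id
  # align consensus (as query) to the reference window; placement must
  # exist -- the consensus was assembled from this very window
  qr <- rmap(consensus$map_id, consensus$fragments)
  loose <- aln_params
  loose$accept_threshold <- Inf
  loose$min_aligned_frags <- 3L
  a <- align_rmap(qr, ref, loose,
                  z2_cap = (aln_params$refine_z_cap %||% Inf)^2)
  if (a$status != "aligned" || a$orientation != "+")
    stop("consensus map could not be aligned to its reference window: ",
         consensus$map_id)
  blocks <- a$blocks
  cb <- map_boundaries(consensus)
  calls <- list()
  add <- function(class, start, end, delta, flo, fhi, cut = NA_real_,
                  cfrag = NA_integer_) {
    calls[[length(calls) + 1L]] <<- data.frame(
      class = class, chrom = chrom, start = start, end = end,
      size_delta_kb = round_mass(delta), ref_frag_lo = flo, ref_frag_hi = fhi,
      cut_bp = cut, consensus_frag = cfrag, suspect = FALSE,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(blocks))) {
    rs <- blocks[k, "ref_start"]; re <- blocks[k, "ref_end"]
    qs <- blocks[k, "q_start"]; qe <- blocks[k, "q_end"]
    # interior query indices -> full consensus fragment indices
    cqs <- qs + 1L; cqe <- qe + 1L
    if (re > rs) { # unmatched reference cuts -> MC
      for (ci in rs:(re - 1L))
        add("MC", rb[ci + 1L], rb[ci + 1L] + 1, 0, rs, re, cut = rb[ci + 1L])
    }
    if (qe > qs) { # unmatched consensus cuts -> EC at scaled position
      qmass <- consensus$fragments[cqs:cqe]
      rspan <- rb[re + 1L] - rb[rs]
      pos <- rb[rs] + cumsum(qmass[-length(qmass)]) * 1000 *
        (rspan / (sum(qmass) * 1000))
      for (p in pos)
        add("EC", round(p), round(p) + 1, 0, rs, re, cut = round(p))
    }
    if (re == rs && qe == qs) {
      r <- ref$fragments[rs]; q <- consensus$fragments[cqs]
      dev <- q - r
      if (abs(dev) + MASS_EPS >= indel_min_deviation(r, thresholds))
        add(if (dev > 0) "INS" else "DEL", rb[rs], rb[rs + 1L], dev, rs, rs,
            cfrag = cqs)
    }
  }
  if (!length(calls))
    return(empty_osa_table())
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$ref_frag_lo, calls$start), , drop = FALSE]
  if (!collapse) { calls$n_diffs <- 1L; return(calls) }
  collapse_other(calls, thresholds)
}

# Classification when the consensus descends from the reference seed and
# carries per-cut provenance: shared cuts partition both maps into
# corresponding segments, so differences read off directly -- no alignment
# ambiguity. Reference cuts absent from the consensus are MCs; novel
# consensus cuts are ECs (placed by linear interpolation between the
# flanking shared cuts); a segment's mass deviation at or beyond
# max(indel_rel * r, indel_min_kb) is an INS/DEL when the segment is
# otherwise difference-free, else it joins the complex-event aggregation.
classify_by_provenance <- function(consensus, reference, thresholds,
                                   collapse = TRUE) {
  chrom <- reference$chrom %||% reference$map_id
  start_bp <- attr(reference, "start_bp") %||% 0
  seed_cuts <- reference$cut_coords
  mg <- merge_frags_with_prov(reference$fragments,
                              seq_len(length(reference$fragments) - 1L),
                              thresholds$merge_min_kb)
  rf <- mg$fragments            # merged reference fragments
  ref_ids <- mg$prov            # surviving seed-cut ids, in order
  rb <- c(start_bp, seed_cuts[ref_ids],
          start_bp + round(sum(reference$fragments) * 1000))
  pc <- attr(consensus, "cut_seed_id")
  # seed cuts merged away on the reference side are below comparison
  # resolution; a consensus cut descending from one is identified with the
  # surviving twin (the nearest retained seed cut), never reported alone
  lost <- setdiff(seq_along(seed_cuts), ref_ids)
  if (length(lost) && any(pc %in% lost, na.rm = TRUE)) {
    for (j in which(pc %in% lost)) {
      twin <- ref_ids[which.min(abs(seed_cuts[ref_ids] - seed_cuts[pc[j]]))]
      pc[j] <- if (twin %in% pc) -1L else twin # -1: invisible duplicate
    }
  }
  pc[!is.na(pc) & pc > 0 & duplicated(pc) & !is.na(pc)] <- -1L
  cb <- map_boundaries(consensus)
  cons_pos <- cb[-c(1L, length(cb))]
  matched <- intersect(ref_ids, pc[!is.na(pc) & pc > 0])
  # rescue pass: a novel consensus cut lying (in mapped reference
  # coordinates) within tolerance of a reference cut with no descendant is
  # re-identified with it -- a cut transiently deleted and re-discovered
  # during refinement is the same cut, not an EC/MC pair
  na_idx <- which(is.na(pc))
  miss_ids <- setdiff(ref_ids, pc)
  if (length(na_idx) && length(miss_ids)) {
    anc_c <- c(cb[1L], cons_pos[match(matched, pc)], cb[length(cb)])
    anc_r <- c(rb[1L], seed_cuts[matched], rb[length(rb)])
    o <- order(anc_c)
    mapped <- stats::approx(anc_c[o], anc_r[o], xout = cons_pos[na_idx],
                            ties = "ordered", rule = 2)$y
    for (id in miss_ids) {
      d <- abs(mapped - seed_cuts[id])
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= thresholds$cut_match_tol_bp &&
          is.na(pc[na_idx[j]])) {
        pc[na_idx[j]] <- id
      }
    }
    matched <- intersect(ref_ids, pc[!is.na(pc) & pc > 0])
  }
  # pattern rescue: when a stretch between two shared cuts contains equally
  # many novel consensus cuts and descendant-less reference cuts, they are
  # one-to-one the same cuts (deleted and re-discovered during refinement,
  # or shifted in position); pair them in order and let the sub-segment
  # masses speak
  repeat {
    sr <- c(0L, sort(match(matched, ref_ids)), length(rf))
    scn <- c(0L, sort(match(matched, pc)), length(consensus$fragments))
    paired <- FALSE
    for (s in seq_len(length(sr) - 1L)) {
      mi <- if (sr[s + 1L] - sr[s] >= 2L) {
        ii <- (sr[s] + 1L):(sr[s + 1L] - 1L)
        ii[!(ref_ids[ii] %in% pc)]
      } else integer(0)
      nj <- if (scn[s + 1L] - scn[s] >= 2L) {
        jj <- (scn[s] + 1L):(scn[s + 1L] - 1L)
        jj[is.na(pc[jj])]
      } else integer(0)
      if (length(mi) && length(mi) == length(nj)) {
        # validate each pair by mapped distance: segment endpoints anchor a
        # linear map from consensus to reference coordinates
        cl_ <- if (scn[s] == 0L) cb[1L] else cons_pos[scn[s]]
        cr_ <- if (scn[s + 1L] == length(consensus$fragments)) cb[length(cb)]
        else cons_pos[scn[s + 1L]]
        rl_ <- rb[sr[s] + 1L]; rr_ <- rb[sr[s + 1L] + 1L]
        cap <- 4 * thresholds$cut_match_tol_bp
        for (t in seq_along(mi)) {
          mapped <- rl_ + (cons_pos[nj[t]] - cl_) / max(cr_ - cl_, 1) *
            (rr_ - rl_)
          if (abs(mapped - seed_cuts[ref_ids[mi[t]]]) <= cap) {
            pc[nj[t]] <- ref_ids[mi[t]]
            paired <- TRUE
          }
        }
      }
    }
    if (!paired) break
    matched <- intersect(ref_ids, pc[!is.na(pc) & pc > 0])
  }
  # segment boundaries: window edges plus shared cuts (in map order)
  ref_cut_at <- function(ids) match(ids, ref_ids)        # merged-ref cut idx
  cons_cut_at <- function(ids) match(ids, pc)            # consensus cut idx
  seg_ref_bounds <- c(0L, sort(ref_cut_at(matched)), length(rf))
  seg_cons_bounds <- c(0L, sort(cons_cut_at(matched)), length(consensus$fragments))
  n_seg <- length(seg_ref_bounds) - 1L
  calls <- list()
  add <- function(class, start, end, delta, flo, fhi, cut = NA_real_,
                  cfrag = NA_integer_) {
    calls[[length(calls) + 1L]] <<- data.frame(
      class = class, chrom = chrom, start = start, end = end,
      size_delta_kb = round_mass(delta), ref_frag_lo = flo, ref_frag_hi = fhi,
      cut_bp = cut, consensus_frag = cfrag, suspect = FALSE,
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_seg)) {
    r_lo <- seg_ref_bounds[s]; r_hi <- seg_ref_bounds[s + 1L]
    c_lo <- seg_cons_bounds[s]; c_hi <- seg_cons_bounds[s + 1L]
    ref_mass <- sum(rf[(r_lo + 1L):r_hi])
    cons_mass <- sum(consensus$fragments[(c_lo + 1L):c_hi])
    # interior reference cuts without a consensus descendant -> MC
    mc_idx <- if (r_hi - r_lo >= 2L) {
      ii <- (r_lo + 1L):(r_hi - 1L)
      ii[!(ref_ids[ii] %in% pc)]
    } else integer(0)
    # interior consensus cuts: novel -> EC; descendants of sub-resolution
    # seed cuts are ignored (below comparison resolution)
    ec_cons_idx <- if (c_hi - c_lo >= 2L) {
      jj <- (c_lo + 1L):(c_hi - 1L)
      jj[is.na(pc[jj])]
    } else integer(0)
    for (ci in mc_idx)
      add("MC", rb[ci + 1L], rb[ci + 1L] + 1, 0, ci, min(ci + 1L, r_hi),
          cut = rb[ci + 1L])
    # map EC positions into reference coordinates
    pl <- cb[c_lo + 1L]; pr <- cb[c_hi + 1L]
    Rl <- rb[r_lo + 1L]; Rr <- rb[r_hi + 1L]
    for (cj in ec_cons_idx) {
      p <- Rl + (cons_pos[cj] - pl) / max(pr - pl, 1) * (Rr - Rl)
      p <- round(min(max(p, Rl + 1), Rr - 1))
      fi <- findInterval(p, rb, rightmost.closed = TRUE)
      fi <- min(max(fi, r_lo + 1L), r_hi)
      add("EC", p, p + 1, 0, fi, fi, cut = p, cfrag = cj)
    }
    # terminal segments have no bounding cut on one side, so their masses
    # are not cut-to-cut measurements; size calls there are unreliable (the
    # overlapping neighbor window sees the same locus as interior). A
    # segment whose reference mass is below the observability floor has
    # bounding cuts that are rarely seen together, so its mass is not
    # measured either.
    dev <- cons_mass - ref_mass
    if (s > 1L && s < n_seg &&
        ref_mass >= (thresholds$min_observable_kb %||% 0) &&
        abs(dev) + MASS_EPS >= indel_min_deviation(ref_mass, thresholds)) {
      add(if (dev > 0) "INS" else "DEL", rb[r_lo + 1L], rb[r_hi + 1L], dev,
          r_lo + 1L, r_hi, cfrag = c_lo + 1L)
      # a segment is a reliable mass measurement only when it is at least
      # the platform resolution and its bounding cuts do not flank
      # sub-observable fragments (whose cut identity is ambiguous)
      obs_floor <- thresholds$min_observable_kb %||% 0
      flank_lo <- if (r_lo >= 1L) rf[r_lo] else Inf
      flank_hi <- if (r_hi < length(rf)) rf[r_hi + 1L] else Inf
      calls[[length(calls)]]$suspect <- ref_mass < 3 ||
        min(flank_lo, flank_hi) < obs_floor
    }
  }
  if (!length(calls)) return(empty_osa_table())
  calls <- do.call(rbind, calls)
  calls <- drop_unobservable_cut_calls(calls, rf, rb, thresholds)
  if (!nrow(calls)) return(empty_osa_table())
  calls <- calls[order(calls$ref_frag_lo, calls$start), , drop = FALSE]
  if (!collapse) { calls$n_diffs <- 1L; return(calls) }
  collapse_other(calls, thresholds)
}

# cut differences flanked by a sub-observable reference fragment reflect
# desorption, not sequence change
drop_unobservable_cut_calls <- function(calls, rf, rb, thresholds) {
  floor_kb <- thresholds$min_observable_kb %||% 0
  if (floor_kb <= 0) return(calls)
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!(calls$class[i] %in% c("EC", "MC"))) next
    ci <- findInterval(calls$cut_bp[i], rb, rightmost.closed = TRUE)
    flanks <- rf[intersect(c(ci - 1L, ci), seq_along(rf))]
    if (length(flanks) && min(flanks) < floor_kb) keep[i] <- FALSE
  }
  calls[keep, , drop = FALSE]
}

empty_osa_table <- function() {
  data.frame(class = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), size_delta_kb = numeric(0),
             ref_frag_lo = integer(0), ref_frag_hi = integer(0),
             cut_bp = numeric(0), consensus_frag = integer(0),
             suspect = logical(0), n_diffs = integer(0),
             stringsAsFactors = FALSE)
}

# chain primitive calls whose reference-fragment indices lie within the
# OTHER aggregation window; chains of >= 2 become a single OTHER call
collapse_other <- function(calls, thresholds) {
  w <- thresholds$other_window_frags
  n <- nrow(calls)
  grp <- integer(n); g <- 1L; grp[1L] <- g
  if (n > 1L) for (i in 2:n) {
    if (calls$ref_frag_lo[i] - calls$ref_frag_hi[i - 1L] <= w - 1L) {
      grp[i] <- g
    } else {
      g <- g + 1L; grp[i] <- g
    }
  }
  out <- lapply(split(seq_len(n), grp), function(ii) {
    if (length(ii) == 1L) {
      r <- calls[ii, , drop = FALSE]; r$n_diffs <- 1L; return(r)
    }
    r <- data.frame(class = "OTHER", chrom = calls$chrom[ii[1L]],
                    start = min(calls$start[ii]), end = max(calls$end[ii]),
                    size_delta_kb = round_mass(sum(calls$size_delta_kb[ii])),
                    ref_frag_lo = min(calls$ref_frag_lo[ii]),
                    ref_frag_hi = max(calls$ref_frag_hi[ii]),
                    cut_bp = NA_real_, consensus_frag = NA_integer_,
                    suspect = any(calls$suspect[ii] %||% FALSE),
                    n_diffs = length(ii), stringsAsFactors = FALSE)
    if (!is.null(calls$n_support)) {
      r$n_support <- max(calls$n_support[ii])
      r$confidence_p <- min(calls$confidence_p[ii])
    }
    if (!is.null(calls$window_id)) r$window_id <- calls$window_id[ii[1L]]
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score the statistical support of an OSA call
#'
#' EC: binomial upper tail for observing `k` concordant cut calls out of
#' `n` spanning molecules if cuts arose spuriously at `false_cut_rate` over
#' the local fragment. MC: binomial lower tail for at most `k` cut
#' observations out of `n` at digestion efficiency `p_d`. INS/DEL:
#' two-sided normal tail for the mean one-to-one block-mass deviation with
#' per-molecule variance `(sizing_cv * r)^2`.
#'
#' @param class `"EC"`, `"MC"`, `"INS"` or `"DEL"`.
#' @param k Supporting observations (concordant cuts, or cut sightings for
#'   MC).
#' @param n Spanning molecules (`> 0`).
#' @param local_ref_kb Local reference fragment mass, kb.
#' @param delta_kb Mean mass deviation (INS/DEL), kb.
#' @param error_params List with `p_d`, `false_cut_rate` (per Mb),
#'   `sizing_cv`.
#' @return The confidence p-value in (0, 1].
#' @export
score_variant <- function(class, k, n, local_ref_kb, delta_kb = 0,
                          error_params = list(p_d = 0.8, false_cut_rate = 5,
                                              sizing_cv = 0.06)) {
  if (n <= 0) stop("no supporting molecules (n = 0)")
  switch(class,
    EC = {
      lambda <- error_params$false_cut_rate * local_ref_kb / 1000
      p_fc <- 1 - exp(-lambda)
      pbinom(k - 1, n, p_fc, lower.tail = FALSE)
    },
    MC = pbinom(k, n, error_params$p_d),
    INS = ,
    DEL = {
      if (delta_kb == 0) return(1)
      se <- error_params$sizing_cv * local_ref_kb / sqrt(n)
      2 * pnorm(-abs(delta_kb) / se)
    },
    OTHER = stop("OTHER calls are scored from their constituent differences"),
    stop("unknown OSA class ", class))
}

#' Call optical structural alterations genome-wide
#'
#' Classifies every assembled window consensus against its reference window,
#' scores each call from the consensus support statistics, applies a
#' Bonferroni cutoff over all tested loci, and de-duplicates calls repeated
#' in overlapping windows (keeping the higher-support record).
#'
#' @param assembly Result of [iterate_assembly()].
#' @param reference The [genome_maps()] used for assembly.
#' @param thresholds A [call_thresholds()].
#' @param error_params Error-model rates used for scoring (see
#'   [score_variant()]).
#' @param aln_params An [alignment_params()].
#' @return List with `calls` (OSA data frame with `confidence_p` and
#'   `n_support`), `per_class` (named counts), `n_tested_loci`.
#' @export
call_genome <- function(assembly, reference, thresholds = call_thresholds(),
                        error_params = list(p_d = 0.8, false_cut_rate = 5,
                                            sizing_cv = 0.06),
                        aln_params = alignment_params()) {
  windows <- assembly$windows
  all_calls <- list()
  n_loci <- 0
  for (w in seq_len(nrow(windows))) {
    cm <- assembly$consensus[[windows$window_id[w]]]
    if (attr(cm, "status") != "assembled") next
    seed <- assembly$seeds[[w]]
    n_loci <- n_loci + 2L * length(seed$fragments) - 1L
    # primitive differences are scored first; only significant ones take
    # part in complex-event aggregation
    calls <- classify_differences(cm, seed, thresholds, aln_params,
                                  collapse = FALSE)
    if (!nrow(calls)) next
    # keep only calls whose locus midpoint lies in the window core (the
    # margin is re-examined by the neighboring windows)
    cmid <- (calls$start + calls$end) / 2
    calls <- calls[cmid >= windows$start[w] &
                   cmid < windows$end[w], , drop = FALSE]
    if (!nrow(calls)) next
    calls$window_id <- windows$window_id[w]
    calls <- score_window_calls(calls, cm, seed, thresholds, error_params)
    all_calls[[length(all_calls) + 1L]] <- calls
  }
  if (!length(all_calls)) {
    tab <- empty_osa_table()
    tab$window_id <- character(0); tab$confidence_p <- numeric(0)
    tab$n_support <- integer(0)
    return(list(calls = tab,
                per_class = setNames(integer(5),
                                     c("EC", "MC", "INS", "DEL", "OTHER")),
                n_tested_loci = n_loci))
  }
  tab <- do.call(rbind, all_calls)
  # Bonferroni over tested loci, applied to primitives
  cutoff <- thresholds$alpha / max(n_loci, 1L)
  tab <- tab[tab$confidence_p <= cutoff, , drop = FALSE]
  # aggregate the surviving primitives into complex events per window
  if (nrow(tab)) {
    tab <- do.call(rbind, lapply(split(tab, tab$window_id), function(wc) {
      wc <- wc[order(wc$ref_frag_lo, wc$start), , drop = FALSE]
      out <- collapse_other(wc, thresholds)
      out$window_id <- wc$window_id[1L]
      out
    }))
    rownames(tab) <- NULL
  }
  # a size call on a suspect segment (below platform resolution, or bounded
  # by cuts flanking sub-observable fragments) must be reproduced by the
  # overlapping neighbor window
  if (nrow(tab)) {
    keep <- rep(TRUE, nrow(tab))
    for (i in which(tab$class %in% c("INS", "DEL") &
                      (tab$suspect %||% FALSE))) {
      mid_i <- (tab$start[i] + tab$end[i]) / 2
      cores <- sum(windows$chrom == tab$chrom[i] &
                     windows$start <= mid_i & windows$end > mid_i)
      if (cores < 2L) next
      corro <- sum(tab$window_id != tab$window_id[i] &
                     (tab$class == tab$class[i] | tab$class == "OTHER") &
                     tab$chrom == tab$chrom[i] &
                     tab$start <= tab$end[i] & tab$end >= tab$start[i])
      if (corro < 1L) keep[i] <- FALSE
    }
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- dedup_window_calls(tab)
  # overlapping windows can report one locus as a specific call and as part
  # of a complex bundle; the specific interpretation wins
  if (nrow(tab) > 1L) {
    drop <- rep(FALSE, nrow(tab))
    oth <- which(tab$class == "OTHER")
    for (i in oth) {
      spec <- which(tab$class != "OTHER" & tab$chrom == tab$chrom[i] &
                    tab$window_id != tab$window_id[i] &
                    tab$start <= tab$end[i] + 1000 &
                    tab$end >= tab$start[i] - 1000)
      if (length(spec)) drop[i] <- TRUE
    }
    tab <- tab[!drop, , drop = FALSE]
  }
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  per_class <- table(factor(tab$class, levels = c("EC", "MC", "INS", "DEL",
                                                  "OTHER")))
  list(calls = tab, per_class = c(unclass(per_class)), n_tested_loci = n_loci)
}

# attach n_support and confidence_p to each call using the consensus
# support bookkeeping
score_window_calls <- function(calls, cm, seed, thresholds, error_params) {
  sup <- attr(cm, "support")
  cov <- attr(cm, "frag_cov")
  nobs <- attr(cm, "frag_n_obs")
  clusters <- attr(cm, "unmatched_clusters")
  ref <- merge_small_fragments(seed, thresholds$merge_min_kb)
  attr(ref, "start_bp") <- attr(seed, "start_bp") %||% 0
  attr(ref, "end_bp") <- attr(seed, "end_bp")
  rb <- map_boundaries(ref)
  cb <- map_boundaries(cm)
  calls$n_support <- 0L
  calls$confidence_p <- 1
  # consensus coordinates drift from the reference by accumulated mass
  # differences; anchor a reference->consensus mapping on cuts with known
  # seed provenance so support lookups hit the right cut
  prov <- attr(cm, "cut_seed_id")
  to_cons <- function(x) x
  if (!is.null(prov) && !is.null(seed$cut_coords)) {
    anc <- which(!is.na(prov) & prov > 0)
    if (length(anc) >= 2L) {
      anc_ref <- seed$cut_coords[prov[anc]]
      anc_cons <- sup$cut_bp[anc]
      ok <- !is.na(anc_ref)
      if (sum(ok) >= 2L)
        to_cons <- function(x) stats::approx(anc_ref[ok], anc_cons[ok],
                                             xout = x, rule = 2,
                                             ties = "ordered")$y
    }
  }
  for (i in seq_len(nrow(calls))) {
    cls <- calls$class[i]
    if (cls == "EC") {
      # the consensus cut this EC descends from (recorded index, else the
      # nearest cut in mapped coordinates)
      j <- if (!is.na(calls$consensus_frag[i]) &&
               calls$consensus_frag[i] <= nrow(sup))
        calls$consensus_frag[i]
      else which.min(abs(sup$cut_bp - to_cons(calls$cut_bp[i])))
      n <- max(sup$spanning[j], 1L); k <- sup$concordant[j]
      fi <- findInterval(calls$cut_bp[i], rb, rightmost.closed = TRUE)
      fi <- min(max(fi, 1L), length(ref$fragments))
      calls$n_support[i] <- k
      calls$confidence_p[i] <- score_variant("EC", k, n, ref$fragments[fi],
                                             error_params = error_params)
    } else if (cls == "MC") {
      # molecules still showing the reference cut appear as an unmatched-cut
      # cluster near the missing site
      cut_cons <- to_cons(calls$cut_bp[i])
      fi <- findInterval(cut_cons, cb, rightmost.closed = TRUE)
      fi <- min(max(fi, 1L), length(cm$fragments))
      n <- max(cov[fi], 1L)
      k <- 0L
      if (nrow(clusters)) {
        near <- abs(clusters$pos_bp - cut_cons) <
          pmax(3 * error_params$sizing_cv * cm$fragments[fi] * 1000, 2000)
        if (any(near)) k <- max(clusters$n[near])
      }
      # a cut bounding a fragment below the desorption limit is unobservable
      # whenever that fragment is lost; fold the loss into the null
      ep <- error_params
      ri <- findInterval(calls$cut_bp[i], rb, rightmost.closed = TRUE)
      flanks <- ref$fragments[intersect(c(ri - 1L, ri),
                                        seq_along(ref$fragments))]
      des_min <- ep$desorption_min_kb %||% 0.8
      des_drop <- ep$desorption_drop_prob %||% 0.75
      if (length(flanks) && min(flanks) < des_min)
        ep$p_d <- ep$p_d * (1 - des_drop)
      calls$n_support[i] <- n - k
      calls$confidence_p[i] <- score_variant("MC", k, n, cm$fragments[fi],
                                             error_params = ep)
    } else if (cls %in% c("INS", "DEL")) {
      fi <- calls$consensus_frag[i]
      n <- max(nobs[fi], 1L)
      r <- ref$fragments[calls$ref_frag_lo[i]]
      calls$n_support[i] <- n
      # a size call needs the depth the assembler itself requires
      calls$confidence_p[i] <- if (n < 5L) 1 else
        score_variant(cls, NA, n, r, delta_kb = calls$size_delta_kb[i],
                      error_params = error_params)
    } else { # OTHER: conservative — best constituent evidence proxy
      fi <- findInterval((calls$start[i] + calls$end[i]) / 2, cb,
                         rightmost.closed = TRUE)
      fi <- min(max(fi, 1L), length(cm$fragments))
      n <- max(cov[fi], 1L)
      calls$n_support[i] <- n
      # a complex event spans >= 2 independent differences; score as the
      # product-like bound of one EC-strength difference
      calls$confidence_p[i] <- score_variant("MC", 0, n,
                                             cm$fragments[fi],
                                             error_params = error_params)
    }
  }
  # cut-difference calls at loci whose reference fragments fall below the
  # desorption limit are the expected signature of small-fragment loss, not
  # of sequence change; they carry no evidential weight
  des_min <- error_params$desorption_min_kb %||% 0.8
  small <- which(ref$fragments < des_min)
  if (length(small)) {
    lo <- rb[small] - 1000; hi <- rb[small + 1L] + 1000
    for (i in seq_len(nrow(calls))) {
      if (!(calls$class[i] %in% c("EC", "MC", "OTHER"))) next
      if (calls$class[i] == "OTHER" &&
          abs(calls$size_delta_kb[i]) >= 1) next
      if (any(calls$start[i] <= hi & calls$end[i] >= lo))
        calls$confidence_p[i] <- 1
    }
  }
  calls
}

# drop duplicate calls discovered independently in overlapping windows:
# same class, intervals within the class's intersection window
dedup_window_calls <- function(tab, rules = intersection_rules()) {
  if (nrow(tab) < 2L) return(tab)
  keep <- rep(TRUE, nrow(tab))
  o <- order(tab$chrom, tab$class, tab$start)
  tab <- tab[o, , drop = FALSE]
  for (i in 2:nrow(tab)) {
    j <- i - 1L
    while (j >= 1L && !keep[j]) j <- j - 1L
    if (j < 1L) next
    if (tab$class[i] != tab$class[j] || tab$chrom[i] != tab$chrom[j]) next
    w <- rules$om_windows[[tab$class[i]]] %||% 0
    if (tab$start[i] - w <= tab$end[j] + w &&
        tab$window_id[i] != tab$window_id[j]) {
      # duplicate: keep the higher-support record
      if (tab$n_support[i] >= tab$n_support[j]) keep[j] <- FALSE
      else keep[i] <- FALSE
    }
  }
  tab[keep, , drop = FALSE]
}

#' Write OSA calls as BED4+ with a TSV sidecar
#'
#' @param calls OSA data frame from [call_genome()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @export
write_osa <- function(calls, prefix) {
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start + 1,
                                                pmax(calls$end, calls$start + 1)),
                               name = calls$class)
  write_bed(gr, paste0(prefix, ".bed"))
  write.table(calls, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
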