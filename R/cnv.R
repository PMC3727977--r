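#' Alignment midpoints per chromosome
#'
#' Each accepted alignment is summarised by the single genomic coordinate at
#' the centre of its reference span; rejected molecules are excluded.
#'
#' @param table Alignment table from [align_batch()].
#' @return Named list (per chromosome) of sorted midpoint coordinates.
#' @export
midpoints <- function(table) {
  acc <- table[table$status == "aligned", , drop = FALSE]
  if (!nrow(acc)) return(setNames(list(), character(0)))
  lapply(split(acc$midpoint, acc$chrom), sort)
}

#' Build normalization intervals from normal-sample midpoints
#'
#' Per chromosome, boundaries are placed so each interval contains exactly
#' `m` midpoints of the normal sample (the last interval holds the
#' remainder). Because the normal's alignment density already reflects local
#' restriction-site density, equal-count intervals normalize the tumor
#' counts: under no copy-number change the tumor count per interval follows
#' one negative-binomial distribution genome-wide.
#'
#' @param normal_midpoints Named list of sorted coordinates (from
#'   [midpoints()]).
#' @param chrom_lengths_bp Named vector of chromosome spans.
#' @param m Normal midpoints per interval (default 10, `>= 2`).
#' @return Data frame: `chrom, start, end, normal_count`.
#' @export
build_intervals <- function(normal_midpoints, chrom_lengths_bp, m = 10L) {
  stopifnot(m >= 2)
  out <- lapply(names(normal_midpoints), function(ch) {
    x <- sort(normal_midpoints[[ch]])
    L <- chrom_lengths_bp[[ch]]
    if (length(x) < m) {
      warning("chromosome ", ch, " has fewer than m normal midpoints; ",
              "using a single whole-chromosome interval")
      return(data.frame(chrom = ch, start = 0, end = L,
                        normal_count = length(x)))
    }
    n_full <- floor(length(x) / m)
    # boundary after every m-th midpoint, midway to the next
    cut_idx <- seq_len(n_full - 1L) * m
    bounds <- floor((x[cut_idx] + x[cut_idx + 1L]) / 2)
    starts <- c(0, bounds); ends <- c(bounds, L)
    counts <- vapply(seq_along(starts), function(i)
      sum(x >= starts[i] & x < ends[i]), integer(1))
    data.frame(chrom = ch, start = starts, end = ends, normal_count = counts)
  })
  do.call(rbind, out)
}

#' Count tumor midpoints per interval
#'
#' @param intervals Data frame from [build_intervals()].
#' @param tumor_midpoints Named list of coordinates.
#' @return `intervals` with a `tumor_count` column.
#' @export
count_in_intervals <- function(intervals, tumor_midpoints) {
  intervals$tumor_count <- vapply(seq_len(nrow(intervals)), function(i) {
    x <- tumor_midpoints[[intervals$chrom[i]]]
    if (is.null(x)) return(0L)
    sum(x >= intervals$start[i] & x < intervals$end[i])
  }, integer(1))
  intervals
}

#' Fit the negative-binomial copy-number emission model
#'
#' The diploid rate `mu` is anchored at the median tumor count across
#' intervals (robust while aberrations cover less than half the genome; a
#' bimodality warning flags likely violations). Dispersion `phi`
#' (`variance = mu + phi * mu^2`) is estimated by method of moments on the
#' counts within `0.5 mu .. 1.5 mu`. Copy state `k` has emission mean
#' `mu * k / 2`, with the state-0 mean floored at `0.05 * mu`.
#'
#' @param tumor_counts Integer vector of per-interval tumor counts.
#' @param states Integer copy-number states modelled.
#' @param stay_prob Per-interval probability of remaining in the same state.
#' @param phi_floor Lower bound on the dispersion. Counts in equal-normal-
#'   count intervals are negative binomial with `size = m` by construction
#'   (Poisson rate times a Gamma-distributed interval width), so callers
#'   that know `m` pass `1/m`.
#' @return A list of class `cnv_model` with `mu`, `phi`, `states`,
#'   `emission_means`, `stay_prob`.
#' @export
fit_model <- function(tumor_counts, states = 0:4, stay_prob = 1 - 1e-4,
                      phi_floor = 0) {
  if (length(tumor_counts) < 20L)
    stop("insufficient data: need >= 20 intervals to fit the model")
  if (any(tumor_counts < 0)) stop("negative interval count")
  mu <- median(tumor_counts)
  if (mu <= 0) stop("median interval count is zero; cannot anchor diploid rate")
  # with sizeable aberrant regions the plain median can land between count
  # modes; anchor on the count value whose +/-25% window captures the most
  # intervals (the dominant mode, i.e. the majority state) and polish with
  # windowed medians
  if (length(unique(tumor_counts)) > 3L) {
    cand <- sort(unique(tumor_counts[tumor_counts > 0]))
    mass <- vapply(cand, function(c0)
      mean(tumor_counts >= 0.75 * c0 & tumor_counts <= 1.25 * c0), numeric(1))
    mu <- max(cand[mass >= max(mass) - 1e-12])
    for (it in 1:3) {
      sel0 <- tumor_counts > 0.7 * mu & tumor_counts < 1.5 * mu
      if (sum(sel0) >= 10) mu <- median(tumor_counts[sel0])
    }
  }
  sel <- tumor_counts >= 0.5 * mu & tumor_counts <= 1.5 * mu
  if (sum(sel) < length(tumor_counts) / 2)
    warning("fewer than half of the intervals lie near the diploid anchor; ",
            "count distribution looks multimodal -- the median-as-diploid ",
            "anchor may be violated")
  x <- tumor_counts[sel]
  v <- var(x); mbar <- mean(x)
  phi <- max((v - mbar) / mbar^2, phi_floor, 0)
  emission_means <- pmax(mu * states / 2, 0.05 * mu)
  structure(list(mu = mu, phi = phi, states = as.integer(states),
                 emission_means = emission_means, stay_prob = stay_prob),
            class = "cnv_model")
}

# negative-binomial log-density with Poisson limit at phi -> 0
nb_loglik <- function(x, mean, phi) {
  if (phi < 1e-8) return(dpois(x, mean, log = TRUE))
  dnbinom(x, size = 1 / phi, mu = mean, log = TRUE)
}

#' Viterbi decoding of copy-number states
#'
#' Standard max-product decoding in log space with negative-binomial
#' emissions and a sticky transition matrix (`stay_prob` on the diagonal,
#' remainder uniform), uniform initial distribution. Run per chromosome.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `tumor_count`.
#' @param model A `cnv_model` from [fit_model()].
#' @return List with `path` (decoded state per interval, in input order) and
#'   `segments` (data frame of maximal constant-state runs: `chrom, start,
#'   end, state, mean_normalized_count, n_intervals`).
#' @export
viterbi_decode <- function(intervals, model) {
  if (any(intervals$tumor_count < 0)) stop("negative interval count")
  S <- length(model$states)
  log_stay <- log(model$stay_prob)
  log_switch <- log((1 - model$stay_prob) / (S - 1L))
  # the last interval per chromosome holds the remainder of the normal
  # midpoints; its emission means scale with its actual normal count
  scale <- rep(1, nrow(intervals))
  if (!is.null(intervals$normal_count) && !is.null(model$norm_m))
    scale <- pmax(intervals$normal_count, 1) / model$norm_m
  path <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    x <- intervals$tumor_count[idx]
    n <- length(idx)
    em <- vapply(seq_len(S), function(s)
      vapply(seq_len(n), function(i)
        nb_loglik(x[i], model$emission_means[s] * scale[idx[i]], model$phi),
        numeric(1)),
      numeric(n))
    em <- matrix(em, nrow = n)
    V <- matrix(-Inf, n, S); bp <- matrix(0L, n, S)
    V[1L, ] <- -log(S) + em[1L, ]
    if (n > 1L) for (t in 2:n) {
      for (s in seq_len(S)) {
        cand <- V[t - 1L, ] + ifelse(seq_len(S) == s, log_stay, log_switch)
        bp[t, s] <- which.max(cand)
        V[t, s] <- cand[bp[t, s]] + em[t, s]
      }
    }
    st <- integer(n)
    st[n] <- which.max(V[n, ])
    if (n > 1L) for (t in (n - 1L):1L) st[t] <- bp[t + 1L, st[t + 1L]]
    path[idx] <- model$states[st]
  }
  segments <- path_to_segments(intervals, path, model)
  list(path = path, segments = segments)
}

path_to_segments <- function(intervals, path, model) {
  out <- lapply(unique(intervals$chrom), function(ch) {
    idx <- which(intervals$chrom == ch)
    runs <- rle(path[idx])
    ends_i <- cumsum(runs$lengths)
    starts_i <- c(1L, head(ends_i, -1L) + 1L)
    data.frame(
      chrom = ch,
      start = intervals$start[idx[starts_i]],
      end = intervals$end[idx[ends_i]],
      state = runs$values,
      mean_normalized_count = vapply(seq_along(runs$values), function(k)
        mean(intervals$tumor_count[idx[starts_i[k]:ends_i[k]]]) / model$mu,
        numeric(1)),
      n_intervals = runs$lengths)
  })
  do.call(rbind, out)
}

# choose the diploid anchor whose decode makes copy 2 the majority state
# (the decode-space analogue of median-as-diploid, valid while aberrations
# cover less than half the genome), then refine the anchor from the
# diploid-decoded intervals
decode_anchored <- function(iv, m, states, stay_prob) {
  mu0 <- m * sum(iv$tumor_count) / max(sum(iv$normal_count), 1)
  if (is.null(iv$normal_count)) stop("intervals lack normal counts")
  if (mu0 <= 0) stop("no tumor counts; cannot anchor diploid rate")
  xn <- iv$tumor_count * m / pmax(iv$normal_count, 1) # normalized counts
  mk_model <- function(mu) {
    # dispersion from counts near the anchor only: a wider window swallows
    # the half-rate (copy-1) cluster and inflates phi
    x <- xn[xn >= 0.75 * mu & xn <= 1.25 * mu]
    phi <- if (length(x) >= 10) max((var(x) - mean(x)) / mean(x)^2, 1 / m)
    else 1 / m
    structure(list(mu = mu, phi = phi, states = as.integer(states),
                   emission_means = pmax(mu * states / 2, 0.05 * mu),
                   stay_prob = stay_prob, norm_m = m), class = "cnv_model")
  }
  score <- function(mu) {
    model <- mk_model(mu)
    dec <- viterbi_decode(iv, model)
    # two rounds of self-consistent refinement from the diploid intervals
    for (it in 1:2) {
      dip <- dec$path == 2L
      if (sum(dip) < 10) break
      model <- mk_model(median(xn[dip]))
      dec <- viterbi_decode(iv, model)
    }
    sc <- pmax(iv$normal_count, 1) / m
    ll <- sum(vapply(seq_len(nrow(iv)), function(i)
      nb_loglik(iv$tumor_count[i],
                model$emission_means[match(dec$path[i], model$states)] * sc[i],
                model$phi), numeric(1)))
    list(model = model, dec = dec, frac2 = mean(dec$path == 2L), ll = ll)
  }
  cands <- unique(round(mu0 * c(1, 4 / 3, 2 / 3, 1.15), 2))
  fits <- lapply(cands, score)
  frac2 <- vapply(fits, `[[`, numeric(1), "frac2")
  ll <- vapply(fits, `[[`, numeric(1), "ll")
  # among anchors that decode a diploid majority, take the best-fitting
  # one (maximizing the diploid fraction itself would reward degenerate
  # undersegmented decodes)
  ok <- frac2 >= 0.5
  if (!any(ok)) ok <- frac2 >= max(frac2) - 0.05
  best <- which(ok)[which.max(ll[ok])]
  if (fits[[best]]$frac2 < 0.5)
    warning("fewer than half of the intervals decode as diploid; the ",
            "diploid anchor may be unreliable")
  list(model = fits[[best]]$model, dec = fits[[best]]$dec)
}

#' Copy-number analysis of one alignment table
#'
#' Convenience wrapper: midpoints, interval counting on normal-defined
#' intervals, totals-anchored model fit, Viterbi decoding.
#'
#' @param tumor_table Alignment table (tumor).
#' @param normal_midpoints Output of [midpoints()] on a normal sample.
#' @param chrom_lengths_bp Named chromosome spans.
#' @param m Normal midpoints per interval.
#' @inheritParams fit_model
#' @return List with `intervals`, `model`, `path`, `segments`.
#' @export
call_cnv <- function(tumor_table, normal_midpoints, chrom_lengths_bp,
                     m = 10L, states = 0:4, stay_prob = 1 - 1e-4) {
  iv <- build_intervals(normal_midpoints, chrom_lengths_bp, m)
  iv <- count_in_intervals(iv, midpoints(tumor_table))
  if (nrow(iv) < 20L)
    stop("insufficient data: need >= 20 intervals to fit the model")
  res <- decode_anchored(iv, m, states, stay_prob)
  list(intervals = iv, model = res$model, path = res$dec$path,
       segments = res$dec$segments)
}

#' Per-slice copy-number analysis and discordance report
#'
#' Runs the full coverage pipeline separately for each source label (tumor
#' slice) on a shared set of normal-defined intervals and reports the
#' intervals whose decoded copy-number state differs between labels —
#' the signature of intra-tumor heterogeneity.
#'
#' @param table Alignment table with `source_label`.
#' @param normal_midpoints Output of [midpoints()] on a normal sample.
#' @param chrom_lengths_bp Named chromosome spans.
#' @param m Normal midpoints per interval.
#' @param labels Labels to analyse (default: all in the data).
#' @inheritParams fit_model
#' @return List with `per_label` (named list of [call_cnv()] results) and
#'   `discordance` (data frame of intervals with per-label states).
#' @export
per_slice_cnv <- function(table, normal_midpoints, chrom_lengths_bp,
                          m = 10L, labels = NULL, states = 0:4,
                          stay_prob = 1 - 1e-4) {
  if (is.null(labels))
    labels <- sort(unique(table$source_label[table$status == "aligned"]))
  iv <- build_intervals(normal_midpoints, chrom_lengths_bp, m)
  per_label <- list()
  for (lb in labels) {
    sub <- table[table$source_label == lb, , drop = FALSE]
    if (sum(sub$status == "aligned") == 0L) {
      warning("label ", lb, " has no aligned molecules; skipped")
      next
    }
    ivl <- count_in_intervals(iv, midpoints(sub))
    res <- tryCatch({
      if (nrow(ivl) < 20L)
        stop("insufficient data: need >= 20 intervals to fit the model")
      r <- decode_anchored(ivl, m, states, stay_prob)
      list(intervals = ivl, model = r$model, path = r$dec$path,
           segments = r$dec$segments)
    }, error = function(e) {
      warning("label ", lb, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) per_label[[lb]] <- res
  }
  disc <- empty_discordance()
  if (length(per_label) >= 2L) {
    states_mat <- vapply(per_label, `[[`, numeric(nrow(iv)), "path")
    differs <- apply(states_mat, 1L, function(z) length(unique(z)) > 1L)
    if (any(differs)) {
      disc <- cbind(iv[differs, c("chrom", "start", "end"), drop = FALSE],
                    as.data.frame(states_mat[differs, , drop = FALSE]))
      rownames(disc) <- NULL
    }
  }
  list(per_label = per_label, discordance = disc)
}

empty_discordance <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Write copy-number segments as BED4+ and interval counts as TSV
#'
#' @param result A [call_cnv()] result.
#' @param prefix Output prefix; writes `<prefix>.segments.bed` and
#'   `<prefix>.intervals.tsv`.
#' @export
write_cnv <- function(result, prefix) {
  seg <- result$segments
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1, seg$end),
                               name = paste0("cn", seg$state))
  write_bed(gr, paste0(prefix, ".segments.bed"))
  write.table(result$intervals, paste0(prefix, ".intervals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
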