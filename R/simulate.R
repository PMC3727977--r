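#' Simulation configuration
#'
#' Parameters of the single-molecule error model and of the sampled tumor.
#' The defaults emulate a high-quality optical mapping run: molecules with a
#' right-skewed length distribution averaging ~420 kb (truncated below
#' 300 kb), 80% digestion efficiency at true sites, five spurious cuts per
#' Mb, 6% multiplicative sizing noise, and desorption of most fragments
#' below 0.8 kb.
#'
#' @param seed Integer seed; all simulator randomness flows from it.
#' @param coverage Fold coverage of the genome by total molecule mass.
#' @param molecule_mean_kb Mean of the (untruncated) gamma length
#'   distribution, kb.
#' @param molecule_min_kb Lower truncation of molecule length, kb.
#' @param molecule_shape Gamma shape parameter (right-skew control).
#' @param digest_efficiency Probability a true recognition site is cut.
#' @param false_cut_rate Expected spurious cuts per Mb of molecule.
#' @param sizing_cv Relative standard deviation of observed fragment mass.
#' @param desorption_min_kb,desorption_drop_prob Fragments below
#'   `desorption_min_kb` are lost (dropped from the molecule) with
#'   probability `desorption_drop_prob`.
#' @param subclones List of subclone descriptions, each a list with `label`,
#'   `fraction` (fractions sum to 1), `copy_profile` (data frame
#'   `chrom,start,end,copy`; `NULL` means diploid everywhere), and
#'   `variant_set` (list of [variant_spec()]; may be empty).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, coverage = 30,
                       molecule_mean_kb = 420, molecule_min_kb = 300,
                       molecule_shape = 8,
                       digest_efficiency = 0.8, false_cut_rate = 5,
                       sizing_cv = 0.06,
                       desorption_min_kb = 0.8, desorption_drop_prob = 0.75,
                       subclones = list(list(label = "s1", fraction = 1,
                                             copy_profile = NULL,
                                             variant_set = list()))) {
  stopifnot(coverage > 0, molecule_mean_kb > 0, molecule_min_kb >= 0,
            molecule_shape > 0, digest_efficiency > 0, digest_efficiency <= 1,
            false_cut_rate >= 0, sizing_cv >= 0,
            desorption_min_kb >= 0, desorption_drop_prob >= 0,
            desorption_drop_prob <= 1, length(subclones) >= 1)
  fr <- vapply(subclones, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("subclone fractions must sum to 1")
  structure(list(seed = as.integer(seed), coverage = coverage,
                 molecule_mean_kb = molecule_mean_kb,
                 molecule_min_kb = molecule_min_kb,
                 molecule_shape = molecule_shape,
                 digest_efficiency = digest_efficiency,
                 false_cut_rate = false_cut_rate, sizing_cv = sizing_cv,
                 desorption_min_kb = desorption_min_kb,
                 desorption_drop_prob = desorption_drop_prob,
                 subclones = subclones),
            class = "sim_config")
}

#' Specification of one implanted variant
#'
#' @param type One of `"INS"`, `"DEL"`, `"INV"`, `"SITE_GAIN"`,
#'   `"SITE_LOSS"`.
#' @param chrom Chromosome name.
#' @param position_bp 0-based position of the variant (left edge).
#' @param size_bp Event size in bp; 0 for site changes.
#' @export
variant_spec <- function(type, chrom, position_bp, size_bp = 0) {
  type <- match.arg(type, c("INS", "DEL", "INV", "SITE_GAIN", "SITE_LOSS"))
  if (type %in% c("INS", "DEL", "INV") && size_bp <= 0)
    stop(type, " requires size_bp > 0")
  list(type = type, chrom = chrom, position_bp = as.numeric(position_bp),
       size_bp = as.numeric(size_bp))
}

#' Simulate a random reference genome
#'
#' I.i.d. bases at the requested GC fraction; a stand-in for a real
#' reference assembly with a realistic recognition-site density (the SwaI
#' site is AT-rich, so lower GC gives denser cutting).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param gc_fraction GC content in (0, 1).
#' @param seed Integer seed.
#' @param enzyme An [enzyme_spec()].
#' @return List with `seqs` (named `DNAStringSet`) and `maps`
#'   (a [genome_maps()] of the digest).
#' @export
simulate_reference <- function(chrom_lengths, gc_fraction = 0.5, seed = 1L,
                               enzyme = enzyme_spec()) {
  stopifnot(gc_fraction > 0, gc_fraction < 1)
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(chrom_lengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- names(chrom_lengths)
  list(seqs = seqs, maps = digest_genome(seqs, enzyme))
}

# random sequence guaranteed free of the recognition site (on either strand
# of a palindromic site one check suffices); also checked in context later.
random_site_free_seq <- function(n, enzyme) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!grepl(enzyme$site, s, fixed = TRUE)) return(s)
  }
}

count_sites <- function(seq_char, enzyme) {
  length(Biostrings::matchPattern(enzyme$site,
                                  Biostrings::DNAString(seq_char),
                                  fixed = TRUE))
}

#' Implant structural variants into a genome
#'
#' Applies non-overlapping variant specs to the sequences. `DEL` removes
#' bases, `INS` inserts novel site-free bases, `INV` reverse-complements the
#' interval, `SITE_GAIN`/`SITE_LOSS` apply a single-base substitution that
#' creates/destroys exactly one recognition site (a "snip-SNP").
#'
#' @param seqs Named `DNAStringSet` (or character vector).
#' @param specs List of [variant_spec()]s.
#' @param enzyme An [enzyme_spec()].
#' @param seed Seed for the novel inserted sequence.
#' @return List with `seqs` (altered genome), `maps` (its digest) and
#'   `truth` (data frame of implanted records with post-implant
#'   coordinates).
#' @export
implant_variants <- function(seqs, specs, enzyme = enzyme_spec(), seed = 1L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  set.seed(seed)
  chars <- setNames(as.character(seqs), names(seqs))
  # validate non-overlap per chromosome
  for (ch in unique(vapply(specs, `[[`, character(1), "chrom"))) {
    sp <- Filter(function(s) s$chrom == ch, specs)
    iv <- t(vapply(sp, function(s)
      c(s$position_bp, s$position_bp + max(s$size_bp, 8)), numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("overlapping variant specs on ", ch)
  }
  truth <- list()
  for (ch in names(chars)) {
    sp <- Filter(function(s) s$chrom == ch, specs)
    if (!length(sp)) next
    sp <- sp[order(vapply(sp, `[[`, numeric(1), "position_bp"))]
    shift <- 0 # cumulative bp offset from upstream INS/DEL
    s <- chars[[ch]]
    for (v in sp) {
      pos <- v$position_bp + shift # post-implant coordinate (0-based)
      if (pos < 0 || pos + v$size_bp > nchar(s))
        stop("variant outside chromosome ", ch)
      if (v$type == "DEL") {
        s <- paste0(substr(s, 1, pos), substr(s, pos + v$size_bp + 1, nchar(s)))
        shift <- shift - v$size_bp
      } else if (v$type == "INS") {
        ins <- random_site_free_seq(v$size_bp, enzyme)
        repeat { # re-draw if the junctions create a site
          cand <- paste0(substr(s, max(1, pos - 6), pos), ins,
                         substr(s, pos + 1, min(nchar(s), pos + 7)))
          before <- paste0(substr(s, max(1, pos - 6), pos),
                           substr(s, pos + 1, min(nchar(s), pos + 7)))
          if (count_sites(cand, enzyme) == count_sites(before, enzyme)) break
          ins <- random_site_free_seq(v$size_bp, enzyme)
        }
        s <- paste0(substr(s, 1, pos), ins, substr(s, pos + 1, nchar(s)))
        shift <- shift + v$size_bp
      } else if (v$type == "INV") {
        seg <- substr(s, pos + 1, pos + v$size_bp)
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
        s <- paste0(substr(s, 1, pos), rc, substr(s, pos + v$size_bp + 1, nchar(s)))
      } else if (v$type == "SITE_GAIN") {
        s <- apply_site_gain(s, pos, enzyme)
      } else if (v$type == "SITE_LOSS") {
        s <- apply_site_loss(s, pos, enzyme)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        type = v$type, chrom = ch, position_bp = pos,
        size_bp = v$size_bp, stringsAsFactors = FALSE)
    }
    chars[[ch]] <- s
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(chars)
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(type = character(0), chrom = character(0),
                  position_bp = numeric(0), size_bp = numeric(0))
  list(seqs = out, maps = digest_genome(out, enzyme), truth = truth)
}

# single-base substitution creating exactly one new site near pos (0-based):
# search outward for a window at Hamming distance 1 from the site.
apply_site_gain <- function(s, pos, enzyme, max_search_bp = 50000) {
  site <- strsplit(enzyme$site, "")[[1L]]
  w <- length(site)
  L <- nchar(s)
  for (d in 0:max_search_bp) {
    for (p in unique(c(pos + d, pos - d))) {
      if (p < 0 || p + w > L) next
      win <- strsplit(substr(s, p + 1, p + w), "")[[1L]]
      mm <- which(win != site)
      if (length(mm) != 1L) next
      cand <- s
      substr(cand, p + mm, p + mm) <- site[mm]
      ctx0 <- substr(s, max(1, p - w + 2), min(L, p + 2 * w - 1))
      ctx1 <- substr(cand, max(1, p - w + 2), min(L, p + 2 * w - 1))
      if (count_sites(ctx1, enzyme) - count_sites(ctx0, enzyme) == 1L)
        return(cand)
    }
  }
  stop("no single-substitution site gain possible near position ", pos)
}

# destroy the recognition site whose window covers/starts near pos
apply_site_loss <- function(s, pos, enzyme, tol_bp = 1000) {
  w <- nchar(enzyme$site)
  L <- nchar(s)
  lo <- max(0, pos - tol_bp); hi <- min(L - w, pos + tol_bp)
  ctx <- substr(s, lo + 1, min(L, hi + w))
  m <- Biostrings::matchPattern(enzyme$site, Biostrings::DNAString(ctx),
                                fixed = TRUE)
  if (length(m) == 0L)
    stop("SITE_LOSS: no recognition site within ", tol_bp, " bp of ", pos)
  starts0 <- lo + BiocGenerics::start(m) - 1L # 0-based site starts
  p <- starts0[which.min(abs(starts0 - pos))]
  site <- strsplit(enzyme$site, "")[[1L]]
  for (i in seq_len(w)) {
    for (repl in setdiff(c("A", "C", "G", "T"), site[i])) {
      cand <- s
      substr(cand, p + i, p + i) <- repl
      ctx1 <- substr(cand, max(1, p - w + 2), min(L, p + 2 * w - 1))
      if (count_sites(ctx1, enzyme) == 0L) return(cand)
    }
  }
  stop("could not destroy site at ", p, " without creating another")
}

# mean of a gamma truncated below at c
truncated_gamma_mean <- function(mean, shape, min) {
  scale <- mean / shape
  num <- mean * stats::pgamma(min, shape + 1, scale = scale, lower.tail = FALSE)
  den <- stats::pgamma(min, shape, scale = scale, lower.tail = FALSE)
  num / den
}

rgamma_trunc <- function(n, mean, shape, min) {
  scale <- mean / shape
  out <- numeric(0)
  while (length(out) < n) {
    x <- rgamma(n, shape = shape, scale = scale)
    out <- c(out, x[x >= min])
  }
  out[seq_len(n)]
}

default_copy_profile <- function(maps) {
  do.call(rbind, lapply(names(maps$maps), function(ch)
    data.frame(chrom = ch, start = 0, end = unname(maps$chrom_lengths_bp[ch]),
               copy = 2, stringsAsFactors = FALSE)))
}

#' Draw single-molecule Rmaps from subclone genomes
#'
#' Molecules are drawn from subclones in proportion to
#' `fraction * regional copy number`, with a random start, gamma length,
#' partial digestion (each true cut retained with probability
#' `digest_efficiency`), Poisson spurious cuts, multiplicative Gaussian
#' sizing noise, desorption of small fragments, and random orientation.
#'
#' @param genomes_by_subclone Named list (one entry per subclone label) of
#'   lists with `maps` (a [genome_maps()] of the subclone's genome).
#' @param config A [sim_config()]; labels must match its `subclones`.
#' @return List with `rmaps` (list of [rmap()], each carrying its truth
#'   record) and `truth` (per-molecule data frame).
#' @export
simulate_rmaps <- function(genomes_by_subclone, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genomes_by_subclone) == 0L) stop("empty subclone set")
  set.seed(config$seed)
  labels <- vapply(config$subclones, `[[`, character(1), "label")
  stopifnot(all(labels %in% names(genomes_by_subclone)))

  # sampling regions: (subclone, chrom, start, end, copy) weighted by
  # fraction * copy * length
  mean_len_kb <- truncated_gamma_mean(config$molecule_mean_kb,
                                      config$molecule_shape,
                                      config$molecule_min_kb)
  mean_len_bp <- mean_len_kb * 1000
  # molecules are placed by their midpoint, drawn within a region in
  # proportion to fraction * copy * length, so coverage follows the
  # (molecule-length smoothed) copy profile without double-counting at
  # copy boundaries; regions touching a chromosome end are extended by half
  # a molecule so the clipped molecules there restore full edge coverage
  regions <- do.call(rbind, lapply(seq_along(config$subclones), function(si) {
    sc <- config$subclones[[si]]
    maps <- genomes_by_subclone[[sc$label]]$maps
    cp <- sc$copy_profile
    if (is.null(cp)) cp <- default_copy_profile(maps)
    cp$label <- sc$label
    cp$chrom_len <- unname(maps$chrom_lengths_bp[cp$chrom])
    ext <- (cp$start == 0) * mean_len_bp / 2 +
      (cp$end == cp$chrom_len) * mean_len_bp / 2
    cp$weight <- sc$fraction * cp$copy * (cp$end - cp$start + ext)
    cp$weight_plain <- sc$fraction * cp$copy * (cp$end - cp$start)
    cp
  }))
  regions <- regions[regions$weight > 0, , drop = FALSE]

  genome_bp <- mean(vapply(genomes_by_subclone,
                           function(g) g$maps$total_length_bp, numeric(1)))
  n_mol <- max(1L, round(config$coverage * (genome_bp / 1000) / mean_len_kb *
                           sum(regions$weight) / sum(regions$weight_plain)))

  region_idx <- sample.int(nrow(regions), n_mol, replace = TRUE,
                           prob = regions$weight)
  lengths_kb <- rgamma_trunc(n_mol, config$molecule_mean_kb,
                             config$molecule_shape, config$molecule_min_kb)
  rmaps <- vector("list", n_mol)
  truth_rows <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    rg <- regions[region_idx[i], ]
    maps <- genomes_by_subclone[[rg$label]]$maps
    chrom_len <- rg$chrom_len
    len_bp <- round(lengths_kb[i] * 1000)
    lo <- rg$start - (rg$start == 0) * len_bp / 2
    hi <- rg$end + (rg$end == chrom_len) * len_bp / 2
    mid <- runif(1, lo, hi)
    start <- max(floor(mid - len_bp / 2), 0)
    end <- min(floor(mid + len_bp / 2), chrom_len)
    if (end - start < 1000) next
    cmap <- maps$maps[[rg$chrom]]
    cuts <- cmap$cut_coords
    cuts <- cuts[cuts > start & cuts < end]
    keep <- runif(length(cuts)) < config$digest_efficiency
    obs <- cuts[keep]
    n_fc <- rpois(1, config$false_cut_rate * (end - start) / 1e6)
    if (n_fc > 0) obs <- c(obs, floor(runif(n_fc, start + 1, end - 1)))
    obs <- sort(unique(obs))
    frag_bp <- diff(c(start, obs, end))
    frag_kb <- frag_bp / 1000
    # desorption on true mass, before sizing measurement
    if (config$desorption_min_kb > 0 && length(frag_kb) > 1L) {
      small <- frag_kb < config$desorption_min_kb
      drop <- small & (runif(length(frag_kb)) < config$desorption_drop_prob)
      if (all(drop)) drop[which.max(frag_kb)] <- FALSE
      frag_kb <- frag_kb[!drop]
    }
    eps <- rnorm(length(frag_kb), 0, config$sizing_cv)
    frag_kb <- pmax(frag_kb * (1 + eps), MASS_RESOLUTION_KB)
    orientation <- if (runif(1) < 0.5) "+" else "-"
    if (orientation == "-") frag_kb <- rev(frag_kb)
    id <- sprintf("mol_%06d", i)
    rmaps[[i]] <- rmap(id, frag_kb, source_label = rg$label,
                       truth = list(true_chrom = rg$chrom,
                                    true_start_bp = start,
                                    true_end_bp = end,
                                    true_orientation = orientation))
    truth_rows[[i]] <- data.frame(
      molecule_id = id, source_label = rg$label, chrom = rg$chrom,
      start_bp = start, end_bp = end, orientation = orientation,
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(rmaps, is.null, logical(1))
  list(rmaps = rmaps[keep], truth = do.call(rbind, truth_rows[keep]))
}

#' Simulate a complete tumor dataset
#'
#' Convenience wrapper: simulates (or accepts) a reference genome, implants
#' each subclone's variants, and draws Rmaps from the mixture.
#'
#' @param reference List with `seqs` and `maps` as returned by
#'   [simulate_reference()].
#' @param config A [sim_config()].
#' @return List with `reference`, `subclone_genomes`, `rmaps`,
#'   `molecule_truth` and `variant_truth` (per-subclone list).
#' @export
simulate_tumor <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  subclone_genomes <- list()
  variant_truth <- list()
  for (k in seq_along(config$subclones)) {
    sc <- config$subclones[[k]]
    if (length(sc$variant_set)) {
      alt <- implant_variants(reference$seqs, sc$variant_set,
                              seed = config$seed + k)
      subclone_genomes[[sc$label]] <- list(seqs = alt$seqs, maps = alt$maps)
      variant_truth[[sc$label]] <- alt$truth
    } else {
      subclone_genomes[[sc$label]] <- list(seqs = reference$seqs,
                                           maps = reference$maps)
      variant_truth[[sc$label]] <- data.frame(
        type = character(0), chrom = character(0),
        position_bp = numeric(0), size_bp = numeric(0))
    }
  }
  sim <- simulate_rmaps(subclone_genomes, config)
  list(reference = reference, subclone_genomes = subclone_genomes,
       rmaps = sim$rmaps, molecule_truth = sim$truth,
       variant_truth = variant_truth)
}
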