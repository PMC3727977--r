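`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures: small simulated genomes and implant-site pickers.
# Variants are implanted in fragments of typical size (20-60 kb) so the
# 13%/4.5 kb calling rule admits a 10 kb event; detectability in optical
# mapping depends on the local fragment mass, and pathological giant
# fragments are excluded by design, not tuned.

test_ref_small <- simulate_reference(c(chrA = 2e6), gc_fraction = 0.4,
                                     seed = 404)

frag_table <- function(genome, chrom) {
  cmap <- genome$maps$maps[[chrom]]
  b <- c(0, cmap$cut_coords, genome$maps$chrom_lengths_bp[[chrom]])
  list(bounds = b, kb = diff(b) / 1000, cuts = cmap$cut_coords)
}

# midpoint of the k-th fragment in [lo_kb, hi_kb] whose start lies in
# [near, near + span)
pick_fragment_mid <- function(ft, lo_kb, hi_kb, near, span = 1e6, k = 1) {
  ii <- which(ft$kb > lo_kb & ft$kb < hi_kb &
              ft$bounds[-length(ft$bounds)] >= near &
              ft$bounds[-length(ft$bounds)] < near + span)
  i <- ii[1 + ((k - 1) %% length(ii))]
  floor((ft$bounds[i] + ft$bounds[i + 1]) / 2)
}

# a cut flanked by two fragments of >= min_kb within [near, near + span)
pick_flanked_cut <- function(ft, min_kb, near, span = 1e6, k = 1) {
  nfrag <- length(ft$kb)
  ii <- which(ft$kb[-nfrag] > min_kb & ft$kb[-1] > min_kb &
              ft$cuts >= near & ft$cuts < near + span)
  ft$cuts[ii[1 + ((k - 1) %% length(ii))]]
}

# the standard five-variant tumor scenario on a given reference
five_variant_specs <- function(genome, chrom, k = 1) {
  ft <- frag_table(genome, chrom)
  L <- genome$maps$chrom_lengths_bp[[chrom]]
  u <- L / 10
  list(variant_spec("INS", chrom, pick_fragment_mid(ft, 25, 60, 1 * u, u, k), 10000),
       variant_spec("DEL", chrom, pick_fragment_mid(ft, 25, 60, 3 * u, u, k), 10000),
       variant_spec("SITE_GAIN", chrom, pick_fragment_mid(ft, 20, 60, 5 * u, u, k)),
       variant_spec("SITE_LOSS", chrom, pick_flanked_cut(ft, 15, 7 * u, 0.9 * u, k)),
       variant_spec("INS", chrom, pick_fragment_mid(ft, 30, 60, 8.5 * u, u, k), 30000))
}

# implanted positions mapped back to reference coordinates (positions in
# the truth table are post-implant)
truth_ref_positions <- function(truth) {
  shift <- cumsum(c(0, head(ifelse(truth$type == "INS", truth$size_bp,
                                   ifelse(truth$type == "DEL",
                                          -truth$size_bp, 0)), -1)))
  truth$position_bp - shift
}

# exhaustive minimum-cost monotone block matching (the alignment oracle):
# every interior query fragment is consumed by contiguous blocks of at most
# delta fragments per side; the reference start is free
oracle_fit_cost <- function(ref, query_interior, sigma, c_ec, c_mc, delta) {
  R <- length(ref); M <- length(query_interior)
  rec <- function(i, j) {
    if (j > M) return(0)
    best <- Inf
    for (a in seq_len(min(delta, R - i))) {
      r <- sum(ref[(i + 1):(i + a)])
      for (b in seq_len(min(delta, M - j + 1))) {
        q <- sum(query_interior[j:(j + b - 1)])
        z <- (q - r) / (sigma * r)
        cost <- z^2 + (b - 1) * c_ec + (a - 1) * c_mc + rec(i + a, j + b)
        if (cost < best) best <- cost
      }
    }
    best
  }
  min(vapply(0:(R - 1), function(s) rec(s, 1), numeric(1)))
}
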