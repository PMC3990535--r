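#' Build a tiling-array probe layout
#'
#' Lays evenly spaced probes along each chromosome (one probe every
#' `spacing_bp` base pairs, the resolution of NimbleGen-style 720K whole
#' genome tiling designs) and scatters them over the physical array grid by a
#' seeded random permutation, so that spatial artifacts on the grid are
#' independent of genomic position.
#'
#' @param n_chrom number of chromosomes (named `"1"`, `"2"`, ...).
#' @param chrom_length_bp chromosome length(s) in bp; recycled to `n_chrom`.
#' @param spacing_bp distance between consecutive probe starts (default
#'   2509 bp, genome-wide median tiling density of the emulated platform).
#' @param grid_dims integer `c(rows, cols)` of the array grid; default is the
#'   smallest near-square grid holding all probes.  An explicit grid smaller
#'   than the probe count is an error.
#' @param seed integer seed for the grid permutation (`NULL` = current RNG).
#' @return a `data.frame` of class `probe_layout` with columns `probe_id`,
#'   `chrom`, `pos` (1-based bp), `grid_x` (column), `grid_y` (row).
#'   Positions are strictly increasing within each chromosome and
#'   `(grid_x, grid_y)` pairs are unique.
#' @export
make_layout <- function(n_chrom = 2L, chrom_length_bp = 2509000,
                        spacing_bp = 2509, grid_dims = NULL, seed = NULL) {
  stopifnot(n_chrom >= 1, spacing_bp > 0, all(chrom_length_bp > 0))
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(chrom_length_bp, n_chrom)
  per_chrom <- floor(lens / spacing_bp)
  total <- sum(per_chrom)
  if (total < 1L) stop("no probes: chromosomes shorter than the probe spacing")

  if (is.null(grid_dims)) {
    rows <- ceiling(sqrt(total))
    grid_dims <- c(rows, ceiling(total / rows))
  }
  capacity <- prod(grid_dims)
  if (capacity < total) {
    stop(sprintf("grid %dx%d holds %d features but layout needs %d probes",
                 grid_dims[1], grid_dims[2], capacity, total))
  }
  cells <- sample.int(capacity, total)          # seeded permutation
  chrom <- rep(as.character(seq_len(n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m) (seq_len(m) - 1) * spacing_bp + 1),
                use.names = FALSE)
  layout <- data.frame(
    probe_id = sprintf("P%06d", seq_len(total)),
    chrom = chrom,
    pos = as.integer(pos),
    grid_x = as.integer((cells - 1L) %% grid_dims[2] + 1L),
    grid_y = as.integer((cells - 1L) %/% grid_dims[2] + 1L),
    stringsAsFactors = FALSE
  )
  attr(layout, "spacing_bp") <- spacing_bp
  attr(layout, "chrom_length_bp") <- lens
  class(layout) <- c("probe_layout", "data.frame")
  layout
}

#' Implant ground-truth copy-number regions into a layout
#'
#' Converts a table of truth regions into a per-probe expected log2-ratio
#' shift track.  Probes whose position falls inside a region (closed
#' interval) carry that region's shift; all other probes are 0 (diploid
#' baseline).  Default shifts are +0.4/-0.4 for gain/loss and +1.3/-1.3 for
#' amplification/deletion, clearing the 0.25 and 1.0 calling thresholds.
#'
#' @param layout a [make_layout()] probe layout.
#' @param regions `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive bp), `cnv_class` (gain/loss/amplification/deletion) and
#'   optionally `log2_shift`.  Regions must be pairwise non-overlapping
#'   within a chromosome.
#' @return list of class `truth_set`: `shift` (numeric, per probe) and
#'   `regions` (the input with `log2_shift` filled in).
#' @export
implant_truth <- function(layout, regions = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  if (is.null(regions) || nrow(regions) == 0L) {
    return(structure(list(shift = numeric(nrow(layout)),
                          regions = empty_truth_regions()),
                     class = "truth_set"))
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "cnv_class")
  if (!all(need %in% names(regions))) {
    stop("truth regions need columns: ", paste(need, collapse = ", "))
  }
  regions$chrom <- as.character(regions$chrom)
  bad_class <- setdiff(regions$cnv_class, names(DEFAULT_SHIFTS))
  if (length(bad_class)) stop("unknown cnv_class: ", paste(bad_class, collapse = ", "))
  if (any(regions$start > regions$end)) stop("truth region with start > end")
  if (any(regions$start < 1)) stop("truth region starts before position 1")
  missing_chrom <- setdiff(regions$chrom, unique(layout$chrom))
  if (length(missing_chrom)) {
    stop("truth regions on chromosomes absent from the layout: ",
         paste(missing_chrom, collapse = ", "))
  }
  lens <- attr(layout, "chrom_length_bp")
  if (!is.null(lens)) {
    len_of <- setNames(lens, unique(layout$chrom))
    if (any(regions$end > len_of[regions$chrom])) {
      stop("truth region extends past its chromosome end")
    }
  }
  if (is.null(regions$log2_shift)) {
    regions$log2_shift <- unname(DEFAULT_SHIFTS[regions$cnv_class])
  }
  wrong_sign <- sign(regions$log2_shift) !=
    ifelse(regions$cnv_class %in% c("gain", "amplification"), 1, -1)
  if (any(wrong_sign)) stop("log2_shift sign inconsistent with cnv_class")
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("overlapping truth regions on chromosome ", ch)
    }
  }
  shift <- numeric(nrow(layout))
  for (i in seq_len(nrow(regions))) {
    hit <- layout$chrom == regions$chrom[i] &
      layout$pos >= regions$start[i] & layout$pos <= regions$end[i]
    shift[hit] <- regions$log2_shift[i]
  }
  structure(list(shift = shift, regions = regions), class = "truth_set")
}

empty_truth_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             cnv_class = character(), log2_shift = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulate two-channel probe intensities
#'
#' Generates Cy3-like test and Cy5-like reference intensities so that the
#' per-probe log2 ratio is exactly
#' `shift + gx*grid_x + gy*grid_y + dye_bias + N(0, noise_sd)`.
#' A shared per-probe affinity term (sd `affinity_sd`) multiplies both
#' channels, giving each channel a realistic intensity spread while
#' cancelling in the ratio; the ratio noise is split symmetrically across
#' the two channels so both stay positive by construction.
#'
#' @param layout a probe layout.
#' @param truth optional [implant_truth()] truth set (default: no CNVs).
#' @param baseline_intensity positive scale of both channels (a.u.).
#' @param noise_sd standard deviation of the per-probe log2-ratio noise.
#' @param gradient `c(gx, gy)` log2 units per grid column/row: a linear
#'   spatial artifact across the physical array.
#' @param dye_bias constant log2 offset added to the test channel.
#' @param affinity_sd sd of the shared per-probe log2 affinity.
#' @param seed optional integer seed.
#' @return the layout with columns `test_intensity` and `ref_intensity`
#'   appended (class `probe_table`).
#' @export
simulate_channels <- function(layout, truth = NULL, baseline_intensity = 1000,
                              noise_sd = 0.15, gradient = c(0, 0),
                              dye_bias = 0, affinity_sd = 1, seed = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  if (baseline_intensity <= 0) stop("baseline_intensity must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(layout)
  shift <- if (is.null(truth)) numeric(n) else truth$shift
  stopifnot(length(shift) == n)
  eps <- rnorm(n, 0, noise_sd)
  aff <- if (affinity_sd > 0) rnorm(n, 0, affinity_sd) else numeric(n)
  mu <- shift + gradient[1] * layout$grid_x + gradient[2] * layout$grid_y + dye_bias
  tab <- layout
  tab$ref_intensity <- baseline_intensity * 2^(aff - eps / 2)
  tab$test_intensity <- baseline_intensity * 2^(aff + mu + eps / 2)
  class(tab) <- c("probe_table", class(layout))
  tab
}

#' Default recurrent-region specification for cohort simulation
#'
#' One recurrent gain (log2 shift +0.4, penetrance 0.6) on the first
#' chromosome and one recurrent amplification (+1.3, penetrance 0.35) on
#' the last, each spanning ~10% of the chromosome's probes (probes 40-50%
#' and 60-70% along, respectively), so the specification scales with the
#' supplied layout.
#'
#' @param layout probe layout the spec must fit (default layout if `NULL`).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `cnv_class`,
#'   `penetrance`.
#' @export
default_recurrent_spec <- function(layout = NULL) {
  if (is.null(layout)) layout <- make_layout()
  chroms <- unique(layout$chrom)
  ch1 <- chroms[1]
  ch2 <- chroms[length(chroms)]
  span <- function(ch, lo, hi) {
    pos <- layout$pos[layout$chrom == ch]
    n <- length(pos)
    c(pos[max(1L, ceiling(lo * n))], pos[max(1L, floor(hi * n))])
  }
  g <- span(ch1, 0.4, 0.5)
  a <- span(ch2, 0.6, 0.7)
  data.frame(
    chrom = c(ch1, ch2),
    start = as.integer(c(g[1], a[1])),
    end = as.integer(c(g[2], a[2])),
    cnv_class = c("gain", "amplification"),
    penetrance = c(0.6, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Simulate an aCGH tumor cohort with recurrent and private CNVs
#'
#' Each sample carries every recurrent region independently with its
#' penetrance (Bernoulli), plus a Poisson number of private CNVs placed
#' uniformly without overlap.  Channel intensities are then simulated per
#' sample with [simulate_channels()].  Default cohort size is 20 samples,
#' mirroring a typical FFPE tumor series.
#'
#' @param n_samples cohort size.
#' @param layout probe layout shared by all samples (default [make_layout()]).
#' @param recurrent_spec `data.frame(chrom, start, end, cnv_class,
#'   penetrance)`; default [default_recurrent_spec()].
#' @param private_cnv_rate expected number of private CNVs per sample.
#' @param private_size_probes length range (in probes) of private CNVs.
#' @param noise_sd,gradient,dye_bias,baseline_intensity,affinity_sd passed to
#'   [simulate_channels()].
#' @param seed integer seed for the whole cohort.
#' @return list of class `cohort_sim`: `samples` (named list of probe
#'   tables), `truth` (per-sample truth region data.frames), `carriage`
#'   (logical matrix samples x recurrent regions), `recurrent_spec`,
#'   `layout`, `sample_ids`.
#' @export
simulate_cohort <- function(n_samples = 20L, layout = NULL,
                            recurrent_spec = NULL, private_cnv_rate = 2,
                            private_size_probes = c(20L, 80L),
                            noise_sd = 0.15, gradient = c(0, 0), dye_bias = 0,
                            baseline_intensity = 1000, affinity_sd = 1,
                            seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(layout)) layout <- make_layout()
  if (is.null(recurrent_spec)) recurrent_spec <- default_recurrent_spec(layout)
  stopifnot(all(recurrent_spec$penetrance >= 0, recurrent_spec$penetrance <= 1))
  spacing <- attr(layout, "spacing_bp") %||% 2509
  lens <- attr(layout, "chrom_length_bp")
  chroms <- unique(layout$chrom)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))

  n_rec <- nrow(recurrent_spec)
  carriage <- matrix(FALSE, n_samples, n_rec,
                     dimnames = list(sample_ids, NULL))
  samples <- vector("list", n_samples)
  truths <- vector("list", n_samples)
  names(samples) <- names(truths) <- sample_ids

  for (s in seq_len(n_samples)) {
    carried <- runif(n_rec) < recurrent_spec$penetrance
    carriage[s, ] <- carried
    regions <- recurrent_spec[carried, c("chrom", "start", "end", "cnv_class"),
                              drop = FALSE]
    n_priv <- rpois(1, private_cnv_rate)
    tries <- 0L
    while (n_priv > 0L && tries < 200L) {
      tries <- tries + 1L
      ch_i <- sample.int(length(chroms), 1)
      npr <- floor(lens[ch_i] / spacing)
      len_p <- sample(seq(private_size_probes[1], private_size_probes[2]), 1)
      if (len_p >= npr) next
      first <- sample.int(npr - len_p, 1)
      start <- as.integer((first - 1) * spacing + 1)
      end <- as.integer((first + len_p - 1) * spacing)
      same <- regions$chrom == chroms[ch_i]
      if (any(same & regions$start <= end & regions$end >= start)) next
      regions <- rbind(regions, data.frame(
        chrom = chroms[ch_i], start = start, end = end,
        cnv_class = sample(names(DEFAULT_SHIFTS), 1),
        stringsAsFactors = FALSE))
      n_priv <- n_priv - 1L
    }
    truth <- implant_truth(layout, regions)
    truths[[s]] <- truth$regions
    samples[[s]] <- simulate_channels(
      layout, truth, baseline_intensity = baseline_intensity,
      noise_sd = noise_sd, gradient = gradient, dye_bias = dye_bias,
      affinity_sd = affinity_sd)
  }
  structure(list(samples = samples, truth = truths, carriage = carriage,
                 recurrent_spec = recurrent_spec, layout = layout,
                 sample_ids = sample_ids),
            class = "cohort_sim")
}

#' Simulate a qPCR Ct table with a known group fold change
#'
#' Generative inverse of the \eqn{2^{-\Delta Ct}} relative-quantification
#' pipeline: control samples are given mean expression
#' `control_mean_expression`, tumor samples `fold` times that, via
#' \eqn{\Delta Ct = -\log_2(\mathrm{expression})}.  Each sample-gene row
#' carries three replicate Ct values for the target and for the reference
#' (housekeeping) gene.  With `ct_sd = 0` and `sample_sd = 0` the realized
#' group fold equals `fold` exactly.
#'
#' @param fold requested tumor/control mean expression ratio (> 0).
#' @param control_mean_expression control-group mean expression (2^-dCt units).
#' @param ct_sd per-replicate Ct noise sd (cycles).
#' @param n_tumor,n_control group sizes (defaults 26 tumors vs 14 normal
#'   muscle controls, the validation design emulated here).
#' @param sample_sd between-sample sd of delta-Ct (cycles); defaults to
#'   `ct_sd`.
#' @param gene,reference_gene labels for the target and housekeeping gene.
#' @param reference_ct mean Ct of the housekeeping gene (cycles).
#' @param seed optional integer seed.
#' @return `data.frame` of class `qpcr_table`: `sample_id`, `group`
#'   (tumor/control), `gene`, `ct_rep1..3`, `ref_ct_rep1..3`.
#' @export
simulate_qpcr <- function(fold, control_mean_expression = 0.5, ct_sd = 0.2,
                          n_tumor = 26L, n_control = 14L, sample_sd = ct_sd,
                          gene = "GLI1", reference_gene = "ACTB",
                          reference_ct = 18, seed = NULL) {
  if (!is.numeric(fold) || fold <= 0) stop("fold must be positive")
  if (control_mean_expression <= 0) stop("control_mean_expression must be positive")
  if (ct_sd < 0 || sample_sd < 0) stop("Ct standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- n_tumor + n_control
  group <- rep(c("tumor", "control"), c(n_tumor, n_control))
  dct_mean <- ifelse(group == "tumor",
                     -log2(fold * control_mean_expression),
                     -log2(control_mean_expression))
  dct <- dct_mean + rnorm(n, 0, sample_sd)
  target_ct <- reference_ct + dct
  rep_noise <- function(mu) sapply(1:3, function(i) mu + rnorm(n, 0, ct_sd))
  tt <- rep_noise(target_ct)
  rr <- rep_noise(rep(reference_ct, n))
  if (any(tt <= 0 | tt >= 45) || any(rr <= 0 | rr >= 45)) {
    stop("simulated Ct values fell outside (0, 45); lower fold or noise")
  }
  tab <- data.frame(
    sample_id = sprintf("%s%02d", ifelse(group == "tumor", "T", "N"),
                        c(seq_len(n_tumor), seq_len(n_control))),
    group = group, gene = gene,
    ct_rep1 = tt[, 1], ct_rep2 = tt[, 2], ct_rep3 = tt[, 3],
    ref_ct_rep1 = rr[, 1], ref_ct_rep2 = rr[, 2], ref_ct_rep3 = rr[, 3],
    stringsAsFactors = FALSE
  )
  attr(tab, "reference_gene") <- reference_gene
  class(tab) <- c("qpcr_table", "data.frame")
  tab
}
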