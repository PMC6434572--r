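# Scoring rules turning raw peak tables into the two dataset variants:
# diploid (two tallest peaks) and polyploid (all peaks within 50% of the
# two main peaks, capped at four alleles).

# Order peaks tallest first; ties broken by smaller fragment size so calls
# are deterministic across platforms.
peak_order <- function(sizes, heights) order(-heights, sizes)

#' Call a diploid genotype from the peaks at one locus
#'
#' No peaks gives a missing call; a single peak is scored as a homozygote
#' (the size repeated); otherwise the two tallest peaks are taken, with
#' height ties broken by the smaller allele size.
#'
#' @param sizes integer fragment sizes (bp).
#' @param heights positive peak heights (fluorescence units).
#' @return integer vector of length 2 (sorted ascending), or `NULL` for a
#'   missing call.
#' @export
call_diploid <- function(sizes, heights) {
  stopifnot(length(sizes) == length(heights))
  if (length(sizes) == 0) return(NULL)
  if (any(heights <= 0)) stop("peak heights must be positive")
  if (any(duplicated(sizes))) stop("duplicate fragment sizes in one locus")
  if (length(sizes) == 1) return(as.integer(c(sizes, sizes)))
  top <- peak_order(sizes, heights)[1:2]
  sort(as.integer(sizes[top]))
}

#' Call a polyploid (chimera-tolerant) genotype from peaks at one locus
#'
#' The two tallest peaks define the main signal; every peak whose height is
#' at least `ratio` times the reference height (by default the lower of the
#' two main peaks) is retained, capped at `max_alleles` tallest peaks.
#' With fewer than two peaks the call equals the diploid call.
#'
#' @inheritParams call_diploid
#' @param ratio height ratio threshold in `(0, 1]`.
#' @param max_alleles ploidy cap (4 = tetraploid).
#' @param reference `"lower"` (default) or `"mean"` of the two main peak
#'   heights.
#' @return integer vector of 1-4 distinct sizes (ascending), or `NULL`.
#' @export
call_polyploid <- function(sizes, heights, ratio = 0.5, max_alleles = 4,
                           reference = c("lower", "mean")) {
  reference <- match.arg(reference)
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  if (length(sizes) == 0) return(NULL)
  if (any(heights <= 0)) stop("peak heights must be positive")
  if (length(sizes) == 1) return(as.integer(sizes))
  ord <- peak_order(sizes, heights)
  main <- heights[ord[1:2]]
  ref <- if (reference == "lower") min(main) else mean(main)
  keep <- ord[heights[ord] >= ratio * ref]
  keep <- keep[seq_len(min(length(keep), max_alleles))]
  sort(as.integer(sizes[keep]))
}

#' Call a whole peak table into a genotype dataset
#'
#' @param peaks peak table (`sample_id`, `population`, `site_group`,
#'   `season`, `locus`, `allele_size_bp`, `peak_height`).
#' @param variant `"diploid"` or `"polyploid"`.
#' @param ratio,max_alleles,reference passed to [call_polyploid()].
#' @return a `genotype_dataset`. Diploid calls store two allele copies per
#'   sample by locus (weight 0.5 each); polyploid calls store distinct
#'   alleles with weight `1 / k`.
#' @export
call_dataset <- function(peaks, variant = c("diploid", "polyploid"),
                         ratio = 0.5, max_alleles = 4, reference = "lower") {
  variant <- match.arg(variant)
  need <- c("sample_id", "population", "locus", "allele_size_bp", "peak_height")
  if (!all(need %in% names(peaks)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (any(peaks$peak_height <= 0)) stop("peak heights must be positive")
  if (!"site_group" %in% names(peaks)) peaks$site_group <- peaks$population
  if (!"season" %in% names(peaks)) peaks$season <- "summer"

  key <- paste(peaks$sample_id, peaks$locus, sep = "\r")
  groups <- split(seq_len(nrow(peaks)), key)
  calls <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    al <- if (variant == "diploid")
      call_diploid(peaks$allele_size_bp[rows], peaks$peak_height[rows])
    else
      call_polyploid(peaks$allele_size_bp[rows], peaks$peak_height[rows],
                     ratio = ratio, max_alleles = max_alleles,
                     reference = reference)
    if (is.null(al)) next
    r1 <- rows[1]
    calls[[gi]] <- data.frame(
      sample_id = peaks$sample_id[r1], locus = peaks$locus[r1],
      allele = if (variant == "diploid") al else unique(al),
      weight = if (variant == "diploid") 0.5 else 1 / length(unique(al)),
      stringsAsFactors = FALSE)
  }
  samples <- unique(peaks[, c("sample_id", "population", "site_group",
                              "season")])
  if (anyDuplicated(samples$sample_id))
    stop("sample_id maps to more than one population/season")
  genotype_dataset(do.call(rbind, calls), samples, variant)
}

#' Flag chimeric colonies and compute per-population chimera proportions
#'
#' A sample is chimeric when its polyploid calls show more than two
#' distinct alleles at one or more loci.
#'
#' @param dataset a polyploid `genotype_dataset`.
#' @return list with `flags` (data frame `sample_id`, `population`,
#'   `is_chimera`) and `cc` (data frame `population`, `n_genotyped`,
#'   `n_chimeric`, `cc` = proportion chimeric).
#' @export
flag_chimeras <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            dataset$variant == "polyploid")
  cnt <- stats::aggregate(allele ~ sample_id + locus, dataset$calls,
                          function(a) length(unique(a)))
  mx <- tapply(cnt$allele, cnt$sample_id, max)
  flags <- data.frame(sample_id = dataset$samples$sample_id,
                      population = dataset$samples$population,
                      stringsAsFactors = FALSE)
  flags$is_chimera <- !is.na(mx[flags$sample_id]) & mx[flags$sample_id] > 2
  cc <- do.call(rbind, lapply(split(flags, flags$population), function(d) {
    data.frame(population = d$population[1], n_genotyped = nrow(d),
               n_chimeric = sum(d$is_chimera),
               cc = mean(d$is_chimera), stringsAsFactors = FALSE)
  }))
  rownames(cc) <- NULL
  list(flags = flags, cc = cc[order(cc$population), ])
}

#' Filter a dataset by missingness
#'
#' Loci whose missingness exceeds `max_missing_per_locus` are dropped
#' first; then samples missing more than `max_missing_loci_per_sample` of
#' the surviving loci are dropped. The removal report is attached as the
#' `"filter_report"` attribute. Filtering is idempotent.
#'
#' @param dataset a `genotype_dataset`.
#' @param max_missing_per_locus maximum tolerated fraction of samples with
#'   a missing call at a locus.
#' @param max_missing_loci_per_sample maximum tolerated number of missing
#'   loci per sample.
#' @return the filtered `genotype_dataset`.
#' @export
filter_dataset <- function(dataset, max_missing_per_locus = 0.10,
                           max_missing_loci_per_sample = 2) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ids <- dataset$samples$sample_id
  has <- unique(dataset$calls[, c("sample_id", "locus")])
  miss_frac <- vapply(dataset$loci, function(loc) {
    1 - sum(has$locus == loc & has$sample_id %in% ids) / length(ids)
  }, numeric(1))
  keep_loci <- dataset$loci[miss_frac <= max_missing_per_locus]
  n_missing <- vapply(ids, function(id) {
    length(keep_loci) - sum(has$sample_id == id & has$locus %in% keep_loci)
  }, numeric(1))
  keep_samples <- ids[n_missing <= max_missing_loci_per_sample]
  if (length(keep_loci) == 0 || length(keep_samples) == 0)
    stop("filtering removed the entire dataset")
  out <- genotype_dataset(
    dataset$calls[dataset$calls$locus %in% keep_loci &
                    dataset$calls$sample_id %in% keep_samples, ],
    dataset$samples[dataset$samples$sample_id %in% keep_samples, ],
    dataset$variant, loci = keep_loci)
  attr(out, "filter_report") <- list(
    dropped_loci = setdiff(dataset$loci, keep_loci),
    dropped_samples = setdiff(ids, keep_samples),
    locus_missingness = miss_frac)
  out
}

#' Replicate concordance
#'
#' Fraction of locus-calls identical between replicate pairs of the same
#' biological sample, per locus and overall; the standard repeatability
#' check for microsatellite scoring.
#'
#' @param dataset a `genotype_dataset`.
#' @param replicate_pairs data frame with columns `sample_a`, `sample_b`.
#' @return list with `overall` (fraction concordant), `per_locus` (named
#'   vector) and `n_compared`.
#' @export
replicate_concordance <- function(dataset, replicate_pairs) {
  stopifnot(all(c("sample_a", "sample_b") %in% names(replicate_pairs)))
  if (nrow(replicate_pairs) == 0) stop("no replicate pairs supplied")
  calls_of <- function(id, loc) {
    sort(dataset$calls$allele[dataset$calls$sample_id == id &
                                dataset$calls$locus == loc])
  }
  res <- expand.grid(pair = seq_len(nrow(replicate_pairs)),
                     locus = dataset$loci, stringsAsFactors = FALSE)
  res$same <- vapply(seq_len(nrow(res)), function(i) {
    a <- calls_of(replicate_pairs$sample_a[res$pair[i]], res$locus[i])
    b <- calls_of(replicate_pairs$sample_b[res$pair[i]], res$locus[i])
    identical(a, b)
  }, logical(1))
  list(overall = mean(res$same),
       per_locus = tapply(res$same, res$locus, mean),
       n_compared = nrow(res))
}
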