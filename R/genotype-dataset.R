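# The called-genotype container and its file formats.

#' Construct a genotype dataset
#'
#' @param calls data frame with columns `sample_id`, `locus`, `allele`
#'   (integer fragment size) and `weight`. Diploid datasets carry exactly
#'   two rows (allele copies, weight 0.5 each) per non-missing sample by
#'   locus; polyploid datasets carry one row per distinct allele with
#'   weight `1 / k`, so every individual contributes total weight 1.
#' @param samples data frame with `sample_id`, `population`, `site_group`,
#'   `season`.
#' @param variant `"diploid"` or `"polyploid"`.
#' @param loci character vector of locus names (defaults to those present).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, samples, variant = c("diploid", "polyploid"),
                             loci = NULL) {
  variant <- match.arg(variant)
  stopifnot(all(c("sample_id", "locus", "allele", "weight") %in% names(calls)),
            all(c("sample_id", "population") %in% names(samples)))
  if (!"site_group" %in% names(samples)) samples$site_group <- samples$population
  if (!"season" %in% names(samples)) samples$season <- "summer"
  calls <- calls[order(calls$sample_id, calls$locus, calls$allele), ]
  structure(list(calls = calls, samples = samples, variant = variant,
                 loci = loci %||% sort(unique(calls$locus))),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %s: %d samples, %d populations, %d loci\n",
              x$variant, nrow(x$samples),
              length(unique(x$samples$population)), length(x$loci)))
  invisible(x)
}

# ---- internal accessors -------------------------------------------------

# Population factor per sample, in a stable order.
gd_pop_factor <- function(dataset, samples = dataset$samples$sample_id) {
  pops <- unique(dataset$samples$population)
  factor(dataset$samples$population[match(samples, dataset$samples$sample_id)],
         levels = pops)
}

# Per-locus diploid genotype table: sample_id, population, a1, a2.
gd_diploid_pairs <- function(dataset, locus) {
  stopifnot(dataset$variant == "diploid")
  cc <- dataset$calls[dataset$calls$locus == locus, ]
  if (nrow(cc) == 0)
    return(data.frame(sample_id = character(0), population = character(0),
                      a1 = integer(0), a2 = integer(0)))
  sp <- split(cc$allele, cc$sample_id)
  bad <- vapply(sp, length, integer(1)) != 2L
  if (any(bad)) stop("diploid dataset has a call without exactly 2 allele copies at ",
                     locus, " (", paste(names(sp)[bad][1]), ")")
  ids <- names(sp)
  a <- vapply(sp, sort, integer(2))
  data.frame(sample_id = ids,
             population = as.character(gd_pop_factor(dataset, ids)),
             a1 = a[1, ], a2 = a[2, ], stringsAsFactors = FALSE,
             row.names = NULL)
}

# Weighted allele counts: list over loci of population x allele matrices.
# For diploid data with weight = "copies", entries are gene-copy counts.
gd_count_matrices <- function(dataset, weighted = (dataset$variant == "polyploid")) {
  pops <- unique(dataset$samples$population)
  out <- lapply(dataset$loci, function(loc) {
    cc <- dataset$calls[dataset$calls$locus == loc, ]
    alleles <- sort(unique(cc$allele))
    m <- matrix(0, length(pops), length(alleles),
                dimnames = list(pops, as.character(alleles)))
    if (nrow(cc) > 0) {
      pi <- factor(match(as.character(gd_pop_factor(dataset, cc$sample_id)),
                         pops), levels = seq_along(pops))
      ai <- factor(match(cc$allele, alleles), levels = seq_along(alleles))
      w <- if (weighted) cc$weight else rep(1, nrow(cc))
      m[] <- as.matrix(stats::xtabs(w ~ pi + ai))
    }
    m
  })
  names(out) <- dataset$loci
  out
}

# Subset a dataset to given sample ids (and drop empty loci if asked).
gd_subset <- function(dataset, sample_ids, drop_loci = FALSE) {
  calls <- dataset$calls[dataset$calls$sample_id %in% sample_ids, ]
  samples <- dataset$samples[dataset$samples$sample_id %in% sample_ids, ]
  loci <- if (drop_loci) sort(unique(calls$locus)) else dataset$loci
  genotype_dataset(calls, samples, dataset$variant, loci)
}

# Subset to one season / population set.
#' Subset a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param season optional season label to keep.
#' @param populations optional population labels to keep.
#' @return a `genotype_dataset`.
#' @export
gd_filter <- function(dataset, season = NULL, populations = NULL) {
  keep <- rep(TRUE, nrow(dataset$samples))
  if (!is.null(season)) keep <- keep & dataset$samples$season %in% season
  if (!is.null(populations))
    keep <- keep & dataset$samples$population %in% populations
  gd_subset(dataset, dataset$samples$sample_id[keep])
}

# ---- file formats -------------------------------------------------------

#' Write a diploid dataset as a GenePop file
#'
#' Three-digit allele codes (the fragment size in base pairs); missing
#' genotypes are written as `000000`.
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param path output file.
#' @param title first line of the file.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(dataset, path, title = "chimerapop export") {
  stopifnot(dataset$variant == "diploid")
  if (max(dataset$calls$allele) > 999)
    stop("allele sizes exceed 999 bp; three-digit GenePop codes impossible")
  loci <- dataset$loci
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  wide <- list()
  for (loc in loci) {
    pr <- gd_diploid_pairs(dataset, loc)
    wide[[loc]] <- stats::setNames(sprintf("%03d%03d", pr$a1, pr$a2),
                                   pr$sample_id)
  }
  for (pop in unique(dataset$samples$population)) {
    writeLines("Pop", con)
    ids <- dataset$samples$sample_id[dataset$samples$population == pop]
    for (id in ids) {
      codes <- vapply(loci, function(loc) {
        v <- wide[[loc]][id]
        if (is.na(v)) "000000" else unname(v)
      }, character(1))
      writeLines(paste0(id, " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GenePop file into a diploid dataset
#'
#' Accepts two- or three-digit allele codes; `00`/`000` means missing.
#'
#' @param path GenePop file.
#' @param season season label to attach.
#' @return a diploid `genotype_dataset` (populations named pop1, pop2, ...
#'   unless sample ids carry their own labels).
#' @export
read_genepop <- function(path, season = "summer") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("not a GenePop file: ", path)
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  pop_idx <- cumsum(is_pop)
  calls <- list(); samples <- list()
  for (i in seq_along(lines)[-seq_len(first_pop - 1)]) {
    if (is_pop[i]) next
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop line: ", lines[i])
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop("sample ", id, " has ", length(codes), " genotype fields for ",
           length(loci), " loci")
    w <- nchar(codes) / 2
    if (any(w != floor(w) | !(nchar(codes) %in% c(4, 6))))
      stop("bad allele code for sample ", id, " (", codes[which(!(nchar(codes) %in% c(4,6)))[1]],
           "): GenePop cells must hold exactly two alleles")
    a1 <- as.integer(substr(codes, 1, w))
    a2 <- as.integer(substr(codes, w + 1, 2 * w))
    ok <- a1 > 0 & a2 > 0
    if (any(ok)) {
      calls[[length(calls) + 1]] <- data.frame(
        sample_id = id,
        locus = rep(loci[ok], each = 2),
        allele = as.vector(rbind(a1[ok], a2[ok])),
        weight = 0.5, stringsAsFactors = FALSE)
    }
    samples[[length(samples) + 1]] <- data.frame(
      sample_id = id, population = paste0("pop", pop_idx[i]),
      stringsAsFactors = FALSE)
  }
  genotype_dataset(do.call(rbind, calls), do.call(rbind, samples),
                   "diploid", loci = loci)
}

#' Write a polyploid dataset as a variable-allele-count CSV
#'
#' One row per sample by locus with up to four allele columns; 0 marks an
#' absent slot, an all-zero row a missing call.
#'
#' @param dataset a polyploid `genotype_dataset`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_polyploid_csv <- function(dataset, path) {
  stopifnot(dataset$variant == "polyploid")
  rows <- list()
  for (loc in dataset$loci) {
    cc <- dataset$calls[dataset$calls$locus == loc, ]
    sp <- split(cc$allele, cc$sample_id)
    for (id in dataset$samples$sample_id) {
      al <- sort(sp[[id]] %||% integer(0))
      al <- c(al, rep(0L, 4 - length(al)))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = id,
        population = dataset$samples$population[
          dataset$samples$sample_id == id],
        locus = loc, a1 = al[1], a2 = al[2], a3 = al[3], a4 = al[4],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a polyploid variable-allele-count CSV
#'
#' @param path CSV written by [write_polyploid_csv()].
#' @param season season label to attach.
#' @return a polyploid `genotype_dataset`.
#' @export
read_polyploid_csv <- function(path, season = "summer") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "locus", "a1", "a2", "a3", "a4")
  if (!all(need %in% names(df)))
    stop("polyploid CSV must have columns: ", paste(need, collapse = ", "))
  calls <- list()
  for (r in seq_len(nrow(df))) {
    al <- unlist(df[r, c("a1", "a2", "a3", "a4")], use.names = FALSE)
    al <- al[al > 0]
    if (length(al) == 0) next
    al <- unique(sort(al))
    calls[[length(calls) + 1]] <- data.frame(
      sample_id = df$sample_id[r], locus = df$locus[r], allele = al,
      weight = 1 / length(al), stringsAsFactors = FALSE)
  }
  samples <- unique(df[, c("sample_id", "population")])
  samples$season <- season
  genotype_dataset(do.call(rbind, calls), samples, "polyploid",
                   loci = sort(unique(df$locus)))
}
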