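#' Construct a genotype matrix
#'
#' The basic container of the package: diploid genotypes for `n` individuals
#' at `m` co-dominant markers. Allele labels are opaque — they are compared
#' for equality only, so integer-coded microsatellite repeat numbers and SNP
#' letters pass through unchanged.
#'
#' @param alleles an `n x m x 2` array of allele labels (character or
#'   numeric). `NA` marks an unobserved allele; both slots of a genotype must
#'   be `NA` together.
#' @param individual_ids character vector of `n` unique individual ids.
#' @param marker_ids character vector of `m` unique marker ids.
#' @return An object of class `genotype_matrix` with elements `alleles`
#'   (character array), `missing` (`n x m` logical matrix, `TRUE` =
#'   genotype unobserved), `individual_ids`, `marker_ids`.
#' @export
genotype_matrix <- function(alleles, individual_ids, marker_ids) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L) {
    stop("`alleles` must be an n x m x 2 array", call. = FALSE)
  }
  n <- dim(alleles)[1]
  m <- dim(alleles)[2]
  if (n < 1L || m < 1L) stop("need at least one individual and one marker", call. = FALSE)
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != n) stop("length(individual_ids) != n", call. = FALSE)
  if (length(marker_ids) != m) stop("length(marker_ids) != m", call. = FALSE)
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  al <- array(as.character(alleles), dim = c(n, m, 2L))
  na1 <- is.na(al[, , 1L, drop = FALSE])[, , 1L, drop = FALSE]
  na2 <- is.na(al[, , 2L, drop = FALSE])[, , 1L, drop = FALSE]
  dim(na1) <- dim(na2) <- c(n, m)
  if (any(na1 != na2)) {
    stop("half-missing genotypes: both allele slots must be observed or missing together",
         call. = FALSE)
  }
  structure(
    list(alleles = al, missing = na1,
         individual_ids = individual_ids, marker_ids = marker_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%.1f%% missing)\n",
              n_individuals(x), n_markers(x), 100 * mean(x$missing)))
  invisible(x)
}

#' Number of individuals / markers in a genotype matrix
#' @param G a [genotype_matrix()].
#' @return An integer.
#' @export
n_individuals <- function(G) length(G$individual_ids)

#' @rdname n_individuals
#' @export
n_markers <- function(G) length(G$marker_ids)

#' Read PLINK PED/MAP genotype files
#'
#' Parses the text PED format: six leading pedigree columns (family id,
#' individual id, father, mother, sex, phenotype) followed by two allele
#' columns per marker. The allele code `"0"` is the PLINK missing code and is
#' mapped to a missing genotype.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the matching `.map` file (marker ids are taken
#'   from its second column; marker order follows the MAP).
#' @return A [genotype_matrix()].
#' @export
read_ped <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) < 2L) stop("MAP file needs at least 2 columns", call. = FALSE)
  marker_ids <- map[[2]]
  m <- length(marker_ids)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PED file: ", ped_path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  bad <- which(lengths(toks) != expected)
  if (length(bad)) {
    stop(sprintf("PED line %d has %d fields; expected %d for %d MAP markers",
                 bad[1], lengths(toks)[bad[1]], expected, m), call. = FALSE)
  }
  n <- length(toks)
  ids <- vapply(toks, `[[`, character(1), 2L)
  al <- array(NA_character_, dim = c(n, m, 2L))
  for (i in seq_len(n)) {
    g <- toks[[i]][-(1:6)]
    al[i, , 1L] <- g[seq(1L, 2L * m, by = 2L)]
    al[i, , 2L] <- g[seq(2L, 2L * m, by = 2L)]
  }
  miss <- al[, , 1L, drop = FALSE] == "0" | al[, , 2L, drop = FALSE] == "0"
  dim(miss) <- c(n, m)
  al[, , 1L][miss] <- NA_character_
  al[, , 2L][miss] <- NA_character_
  genotype_matrix(al, ids, marker_ids)
}

#' Read a tabular genotype file
#'
#' Reads the package's simple TSV dialect: a header row with the individual
#' id column first and two columns per marker named `<marker>.1` and
#' `<marker>.2`; one row per individual. Any allele equal to
#' `missing_sentinel` (by default any non-positive integer code) marks the
#' genotype as missing.
#'
#' @param path path to the TSV file.
#' @param missing_sentinel allele codes to treat as missing. The default
#'   `NULL` masks any allele that parses as a non-positive number.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, missing_sentinel = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 3L) {
    stop("empty or malformed genotype table: ", path, call. = FALSE)
  }
  ids <- df[[1]]
  gcols <- names(df)[-1]
  if (length(gcols) %% 2L != 0L) {
    stop("odd number of allele columns; each marker needs a .1 and .2 column",
         call. = FALSE)
  }
  marker_ids <- unique(sub("\\.[12]$", "", gcols))
  m <- length(marker_ids)
  if (2L * m != length(gcols)) {
    stop("allele columns do not pair up into <marker>.1/<marker>.2", call. = FALSE)
  }
  n <- nrow(df)
  al <- array(NA_character_, dim = c(n, m, 2L))
  for (j in seq_len(m)) {
    al[, j, 1L] <- df[[paste0(marker_ids[j], ".1")]]
    al[, j, 2L] <- df[[paste0(marker_ids[j], ".2")]]
  }
  is_missing_code <- function(x) {
    if (is.null(missing_sentinel)) {
      v <- suppressWarnings(as.numeric(x))
      !is.na(v) & v <= 0
    } else {
      x %in% as.character(missing_sentinel)
    }
  }
  miss <- is_missing_code(al[, , 1L]) | is_missing_code(al[, , 2L])
  dim(miss) <- c(n, m)
  al[, , 1L][miss] <- NA_character_
  al[, , 2L][miss] <- NA_character_
  genotype_matrix(al, ids, marker_ids)
}

#' Estimate allele frequencies by counting
#'
#' Plain counting estimator: the frequency of allele `a` at a marker is the
#' number of observed copies of `a` divided by the total number of observed
#' allele copies at that marker. No pseudo-counts are added, so alleles
#' absent from the (non-excluded) sample are simply absent from the map.
#' Frequencies feed the IBD likelihood, which depends on the allele
#' frequencies of the population under study.
#'
#' @param G a [genotype_matrix()].
#' @param exclude optional integer vector (or pair of ids) of individuals to
#'   leave out of the counts — typically the focal pair, to avoid the small
#'   bias from including it. Default: none excluded.
#' @return An object of class `allele_freqs`: list with `freqs` (per-marker
#'   named numeric vectors summing to 1), `counts` (observed allele copies
#'   per marker), `flagged` (markers with no data, excluded downstream) and
#'   `marker_ids`.
#' @export
estimate_allele_freqs <- function(G, exclude = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- seq_len(n_individuals(G))
  if (!is.null(exclude)) {
    if (is.character(exclude)) exclude <- match(exclude, G$individual_ids)
    if (anyNA(exclude)) stop("unknown individual in `exclude`", call. = FALSE)
    keep <- setdiff(keep, as.integer(exclude))
  }
  m <- n_markers(G)
  freqs <- vector("list", m)
  counts <- integer(m)
  for (j in seq_len(m)) {
    a <- c(G$alleles[keep, j, 1L], G$alleles[keep, j, 2L])
    a <- a[!is.na(a)]
    counts[j] <- length(a)
    if (length(a) == 0L) {
      freqs[j] <- list(NULL)
    } else {
      tab <- table(a)
      freqs[[j]] <- stats::setNames(as.numeric(tab) / length(a), names(tab))
    }
  }
  flagged <- counts == 0L
  if (any(flagged)) {
    warning(sum(flagged), " marker(s) with no observed genotypes flagged and excluded",
            call. = FALSE)
  }
  structure(list(freqs = freqs, counts = counts, flagged = flagged,
                 marker_ids = G$marker_ids),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  k <- lengths(x$freqs)
  cat(sprintf("<allele_freqs> %d markers; alleles per marker: %d-%d; %d flagged\n",
              length(x$freqs), min(k), max(k), sum(x$flagged)))
  invisible(x)
}

#' Build an allele-frequency object from given per-marker frequencies
#'
#' Convenience constructor used mainly with the gene-dropping simulator:
#' either one frequency vector recycled across all markers (e.g. 10
#' equifrequent alleles) or a list with one vector per marker.
#'
#' @param freqs a named numeric vector of allele frequencies (recycled for
#'   every marker) or a list of `n_markers` such vectors. Unnamed vectors get
#'   allele labels `1..k`.
#' @param n_markers number of markers.
#' @param marker_ids optional marker ids; default `M1..Mm`.
#' @return An `allele_freqs` object.
#' @export
allele_freqs <- function(freqs, n_markers, marker_ids = NULL) {
  if (!is.list(freqs)) freqs <- rep(list(freqs), n_markers)
  if (length(freqs) != n_markers) stop("need one frequency vector per marker", call. = FALSE)
  freqs <- lapply(freqs, function(f) {
    nm <- names(f)
    f <- as.numeric(f) / sum(f)
    names(f) <- if (is.null(nm)) as.character(seq_along(f)) else nm
    if (any(f <= 0)) stop("all supplied allele frequencies must be positive", call. = FALSE)
    f
  })
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(n_markers))
  structure(list(freqs = freqs, counts = rep(NA_integer_, n_markers),
                 flagged = rep(FALSE, n_markers), marker_ids = as.character(marker_ids)),
            class = "allele_freqs")
}

#' Equifrequent allele frequencies
#'
#' @param n_alleles number of alleles per marker.
#' @param n_markers number of markers.
#' @return An `allele_freqs` object with `n_alleles` alleles of frequency
#'   `1/n_alleles` at every marker.
#' @export
equifrequent_freqs <- function(n_alleles, n_markers) {
  allele_freqs(rep(1 / n_alleles, n_alleles), n_markers)
}
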