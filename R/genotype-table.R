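#' Construct a GenotypeTable
#'
#' Builds the package's central data object from raw vectors/arrays. Allele
#' pairs are sorted into canonical (ascending) order so genotype equality is
#' independent of the order alleles were recorded in.
#'
#' @param ids character vector of unique individual ids.
#' @param sites character vector of site labels, parallel to \code{ids}.
#' @param loci ordered character vector of locus names.
#' @param alleles integer array \code{n x L x 2} of allele sizes; use
#'   \code{NA} for both copies of a missing genotype. A genotype with exactly
#'   one \code{NA} allele is treated as missing, with a warning.
#' @param coords optional data.frame with columns \code{site}, \code{lat},
#'   \code{lon} (decimal degrees, WGS84).
#' @param siteLevels declared set of site labels; defaults to the labels
#'   present.
#' @return A validated \linkS4class{GenotypeTable}.
#' @export
#' @examples
#' a <- array(c(1L, 1L, 2L, 3L), dim = c(2, 1, 2))
#' gt <- genotypeTable(c("i1", "i2"), c("A", "A"), "L1", a)
#' genotypes(gt, "L1")
genotypeTable <- function(ids, sites, loci, alleles, coords = NULL,
                          siteLevels = NULL) {
  ids <- as.character(ids)
  sites <- as.character(sites)
  loci <- as.character(loci)
  storage.mode(alleles) <- "integer"
  half <- xor(is.na(alleles[, , 1, drop = FALSE]),
              is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) set to MISSING")
    hm <- matrix(half, nrow = dim(alleles)[1])
    idx <- which(hm, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      alleles[idx[r, 1], idx[r, 2], ] <- NA_integer_
    }
  }
  # canonical sort of each pair
  a1 <- alleles[, , 1, drop = FALSE]; a2 <- alleles[, , 2, drop = FALSE]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  alleles[, , 1] <- lo; alleles[, , 2] <- hi
  dimnames(alleles) <- list(ids, loci, c("a1", "a2"))
  coords <- coords %||% data.frame(site = character(), lat = numeric(),
                                   lon = numeric())
  new("GenotypeTable", ids = ids, sites = sites,
      siteLevels = siteLevels %||% unique(sites), loci = loci,
      alleles = alleles, coords = as.data.frame(coords))
}

#' @describeIn genotypeTable number of individuals
#' @param x a GenotypeTable.
#' @export
nInd <- function(x) length(x@ids)

#' @describeIn genotypeTable individual ids
#' @export
indIds <- function(x) x@ids

#' @describeIn genotypeTable site label per individual
#' @export
siteLabels <- function(x) x@sites

#' @describeIn genotypeTable locus names
#' @export
lociNames <- function(x) x@loci

#' @describeIn genotypeTable site coordinates (data.frame site/lat/lon)
#' @export
siteCoordinates <- function(x) x@coords

#' @describeIn genotypeTable n x 2 allele matrix at one locus (NA = missing)
#' @param locus locus name.
#' @export
genotypes <- function(x, locus) {
  if (!locus %in% x@loci) stop("unknown locus: ", locus)
  m <- x@alleles[, locus, , drop = FALSE]
  matrix(m, ncol = 2, dimnames = list(x@ids, c("a1", "a2")))
}

#' Subset a GenotypeTable by individuals
#'
#' @param x a GenotypeTable.
#' @param keep logical or integer index, or character ids.
#' @param dropSites drop unused site levels (default FALSE).
#' @return a GenotypeTable.
#' @export
subsetIndividuals <- function(x, keep, dropSites = FALSE) {
  if (is.character(keep)) keep <- match(keep, x@ids)
  ids <- x@ids[keep]
  sites <- x@sites[keep]
  al <- x@alleles[keep, , , drop = FALSE]
  genotypeTable(ids, sites, x@loci, al, coords = x@coords,
                siteLevels = if (dropSites) unique(sites) else x@siteLevels)
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nInd(object), "individuals,",
      length(object@loci), "loci,",
      length(unique(object@sites)), "site(s)\n")
  miss <- mean(is.na(object@alleles[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%", 100 * miss))
  if (nrow(object@coords)) cat("; coordinates attached")
  cat("\n")
})

#' Read a genotype table from CSV or Genepop
#'
#' CSV dialect: a header row naming \code{id}, \code{site} and either two
#' columns per locus (\code{<locus>_1}, \code{<locus>_2}) or one
#' \code{"a/b"} column per locus.  Genepop dialect: title line, locus names
#' (one per line or comma-separated), \code{POP} blocks with lines
#' \code{"id , 003003 004005 ..."}; \code{000} codes missing alleles.
#'
#' @param path path to the genotype file.
#' @param dialect \code{"csv"} or \code{"genepop"}.
#' @param missingCodes allele codes interpreted as missing (default 0).
#' @param coordsPath optional CSV of site coordinates (columns site, lat,
#'   lon).
#' @param minLoci individuals with fewer non-missing loci are rejected and
#'   reported via a \code{"rejected"} attribute (default 1).
#' @return a \linkS4class{GenotypeTable}; attribute \code{rejected} lists ids
#'   removed by the \code{minLoci} filter.
#' @export
readGenotypeTable <- function(path, dialect = c("csv", "genepop"),
                              missingCodes = 0, coordsPath = NULL,
                              minLoci = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- if (dialect == "csv") parseGenotypeCsv(path, missingCodes)
            else parseGenepop(path, missingCodes)
  n <- length(parsed$ids)
  nonMiss <- rowSums(matrix(!is.na(parsed$alleles[, , 1]), nrow = n))
  minLoci <- max(minLoci, 1)
  rejected <- parsed$ids[nonMiss < minLoci]
  if (length(rejected) == n)
    stop("all individuals fall below minLoci = ", minLoci)
  keep <- nonMiss >= minLoci
  gt <- genotypeTable(parsed$ids[keep], parsed$sites[keep], parsed$loci,
                      parsed$alleles[keep, , , drop = FALSE])
  if (!is.null(coordsPath)) {
    co <- read.csv(coordsPath, stringsAsFactors = FALSE)
    names(co) <- tolower(names(co))
    if (!all(c("site", "lat", "lon") %in% names(co)))
      stop("coordinates file needs columns site, lat, lon")
    gt@coords <- co[, c("site", "lat", "lon")]
  }
  attr(gt, "rejected") <- rejected
  gt
}

parseGenotypeCsv <- function(path, missingCodes) {
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE),
                  error = function(e) stop("empty or unreadable genotype ",
                                           "file: ", path))
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("empty genotype file: ", path)
  names(raw)[1:2] <- tolower(names(raw)[1:2])
  if (!all(c("id", "site") %in% names(raw)[1:2]))
    stop("csv header must start with columns id, site")
  gcols <- names(raw)[-(1:2)]
  paired <- grepl("_[12]$", gcols)
  if (all(paired)) {
    lociAll <- sub("_[12]$", "", gcols)
    loci <- unique(lociAll)
    if (length(gcols) %% 2 != 0 ||
        !all(paste0(rep(loci, each = 2), c("_1", "_2")) %in% gcols))
      stop("odd or mismatched allele column count")
    n <- nrow(raw)
    al <- array(NA_integer_, c(n, length(loci), 2))
    for (j in seq_along(loci)) {
      for (k in 1:2) {
        v <- raw[[paste0(loci[j], "_", k)]]
        al[, j, k] <- parseAlleleColumn(v, missingCodes, path)
      }
    }
  } else if (!any(paired)) {
    loci <- gcols
    n <- nrow(raw)
    al <- array(NA_integer_, c(n, length(loci), 2))
    for (j in seq_along(loci)) {
      parts <- strsplit(as.character(raw[[gcols[j]]]), "/", fixed = TRUE)
      bad <- which(lengths(parts) != 2)
      if (length(bad))
        stop("unparseable rows (expected a/b genotypes) at data row(s): ",
             paste(bad, collapse = ", "))
      m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
      al[, j, 1] <- parseAlleleColumn(m[, 1], missingCodes, path)
      al[, j, 2] <- parseAlleleColumn(m[, 2], missingCodes, path)
    }
  } else stop("mixed genotype column styles: use <locus>_1/_2 or a/b columns")
  list(ids = as.character(raw$id), sites = as.character(raw$site),
       loci = loci, alleles = al)
}

parseAlleleColumn <- function(v, missingCodes, path) {
  v <- trimws(as.character(v))
  out <- suppressWarnings(as.integer(v))
  bad <- which(!is.na(v) & v != "" & is.na(out))
  if (length(bad))
    stop("unparseable allele value(s) in ", path, " at data row(s): ",
         paste(head(bad, 10), collapse = ", "))
  out[out %in% missingCodes] <- NA_integer_
  if (any(out < 0, na.rm = TRUE))
    stop("negative allele size; declare the code in missingCodes if it marks ",
         "missing data")
  out
}

parseGenepop <- function(path, missingCodes) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("empty or truncated genepop file: ", path)
  body <- lines[-1]
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("no POP block in genepop file")
  lociLines <- body[seq_len(popIdx[1] - 1)]
  loci <- trimws(unlist(strsplit(lociLines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); sites <- character(); rows <- list()
  popNo <- 0
  i <- popIdx[1]
  while (i <= length(body)) {
    if (grepl("^\\s*pop\\s*$", body[i], ignore.case = TRUE)) {
      popNo <- popNo + 1
      i <- i + 1
      next
    }
    parts <- strsplit(body[i], ",")[[1]]
    if (length(parts) != 2)
      stop("unparseable genepop line ", i + 1, ": ", body[i])
    label <- trimws(parts[1])
    if (grepl(":", label, fixed = TRUE)) {
      sl <- strsplit(label, ":", fixed = TRUE)[[1]]
      site <- sl[1]; id <- sl[2]
    } else {
      site <- paste0("POP", popNo); id <- label
    }
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("genepop line ", i + 1, ": expected ", length(loci),
           " genotypes, found ", length(codes))
    w <- nchar(codes[1]) / 2
    a1 <- as.integer(substr(codes, 1, w))
    a2 <- as.integer(substr(codes, w + 1, 2 * w))
    a1[a1 %in% c(0, missingCodes)] <- NA_integer_
    a2[a2 %in% c(0, missingCodes)] <- NA_integer_
    a1[is.na(a2)] <- NA_integer_; a2[is.na(a1)] <- NA_integer_
    ids <- c(ids, id); sites <- c(sites, site)
    rows[[length(rows) + 1]] <- cbind(a1, a2)
    i <- i + 1
  }
  n <- length(ids)
  al <- array(NA_integer_, c(n, length(loci), 2))
  for (r in seq_len(n)) al[r, , ] <- rows[[r]]
  list(ids = ids, sites = sites, loci = loci, alleles = al)
}

#' Write a genotype table
#'
#' Canonical writers for both supported dialects; \code{readGenotypeTable}
#' round-trips their output.
#'
#' @param x a GenotypeTable.
#' @param path output file.
#' @param dialect \code{"csv"} or \code{"genepop"}.
#' @return invisibly, \code{path}.
#' @export
writeGenotypeTable <- function(x, path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(id = x@ids, site = x@sites, check.names = FALSE)
    for (j in seq_along(x@loci)) {
      df[[paste0(x@loci[j], "_1")]] <- x@alleles[, j, 1]
      df[[paste0(x@loci[j], "_2")]] <- x@alleles[, j, 2]
    }
    for (col in names(df)[-(1:2)]) df[[col]][is.na(df[[col]])] <- 0L
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (max(x@alleles, na.rm = TRUE) > 999)
      stop("genepop 3-digit codes cannot hold allele sizes > 999")
    con <- file(path, "w"); on.exit(close(con))
    writeLines("kinpatch genotype export", con)
    writeLines(x@loci, con)
    for (s in unique(x@sites)) {
      writeLines("POP", con)
      for (i in which(x@sites == s)) {
        a1 <- x@alleles[i, , 1]; a2 <- x@alleles[i, , 2]
        a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
        codes <- sprintf("%03d%03d", a1, a2)
        writeLines(sprintf("%s:%s, %s", s, x@ids[i],
                           paste(codes, collapse = " ")), con)
      }
    }
  }
  invisible(path)
}

#' Write site coordinates to CSV
#' @param x a GenotypeTable with coordinates attached.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCoordinates <- function(x, path) {
  if (!nrow(x@coords)) stop("no coordinates attached")
  write.csv(x@coords, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
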