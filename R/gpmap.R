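#' Construct a combinatorially complete genotype-phenotype map
#'
#' A `gpmap` holds one record per genotype of a combinatorially complete map:
#' the genotype string (one state label per mutated site, site 1 leftmost),
#' the replicate-mean phenotype, the replicate standard deviation, and the
#' replicate count. Completeness means every combination of site states is
#' present exactly once (`2^L` genotypes for `L` biallelic sites; e.g. 128
#' genotypes for two 4-state nucleotide sites plus three biallelic sites).
#'
#' @param data data.frame with columns `genotype` (character), `phenotype`
#'   (numeric), `stdev` (numeric, >= 0) and `n` (integer, >= 1). `stdev`
#'   and `n` default to 0 and 1 when absent.
#' @param sites optional list of per-site character vectors of allowed state
#'   labels (2 to 4 states each). Inferred from the genotype strings when
#'   omitted.
#' @param wildtype the wild-type genotype string. Defaults to all-"0" when
#'   every site uses the "0"/"1" labels; otherwise it must be supplied.
#' @return An object of class `gpmap`: a list with elements `sites` (list of
#'   per-site state-label vectors), `wildtype` (string) and `data` (the
#'   validated data.frame, in input record order).
#' @examples
#' m <- gpmap(data.frame(genotype = c("00", "01", "10", "11"),
#'                       phenotype = c(0, 2, 1, 2)))
#' n_sites(m)
#' @export
gpmap <- function(data, sites = NULL, wildtype = NULL) {
  stopifnot(is.data.frame(data))
  req <- c("genotype", "phenotype")
  if (!all(req %in% names(data)))
    stop("map data must have columns 'genotype' and 'phenotype'", call. = FALSE)
  data$genotype <- as.character(data$genotype)
  data$phenotype <- as.numeric(data$phenotype)
  if (is.null(data$stdev)) data$stdev <- 0
  if (is.null(data$n)) data$n <- 1L
  data$stdev <- as.numeric(data$stdev)
  data$n <- as.integer(data$n)
  data <- data[, c("genotype", "phenotype", "stdev", "n")]

  nch <- nchar(data$genotype)
  if (length(unique(nch)) != 1L)
    stop("genotype strings have unequal lengths", call. = FALSE)
  L <- nch[1]
  chars <- do.call(rbind, strsplit(data$genotype, ""))

  if (is.null(sites)) {
    sites <- lapply(seq_len(L), function(i) sort(unique(chars[, i])))
  }
  if (length(sites) != L)
    stop("number of sites does not match genotype string length", call. = FALSE)
  for (i in seq_len(L)) {
    st <- sites[[i]]
    if (anyDuplicated(st)) stop("duplicate state labels at site ", i, call. = FALSE)
    if (length(st) < 2 || length(st) > 4)
      stop("site ", i, " has ", length(st),
           " states; between 2 and 4 are supported", call. = FALSE)
    bad <- !chars[, i] %in% st
    if (any(bad))
      stop("invalid state label '", chars[which(bad)[1], i], "' at site ", i,
           call. = FALSE)
  }

  if (is.null(wildtype)) {
    if (all(vapply(sites, function(s) identical(sort(s), c("0", "1")), TRUE))) {
      wildtype <- strrep("0", L)
    } else {
      stop("wildtype genotype must be supplied for non-binary state labels",
           call. = FALSE)
    }
  }
  wt_chars <- strsplit(wildtype, "")[[1]]
  if (length(wt_chars) != L ||
      !all(vapply(seq_len(L), function(i) wt_chars[i] %in% sites[[i]], TRUE)))
    stop("wildtype '", wildtype, "' is not a valid genotype for these sites",
         call. = FALSE)

  # completeness: every state combination exactly once
  expected <- do.call(expand.grid,
                      c(rev(sites), list(stringsAsFactors = FALSE)))
  expected <- apply(expected[, rev(seq_len(L)), drop = FALSE], 1, paste,
                    collapse = "")
  dup <- data$genotype[duplicated(data$genotype)]
  if (length(dup))
    stop("duplicate genotype(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(expected, data$genotype)
  if (length(missing))
    stop("incomplete map: missing genotype(s) ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  extra <- setdiff(data$genotype, expected)
  if (length(extra))
    stop("unexpected genotype(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!wildtype %in% data$genotype)
    stop("wildtype genotype absent from map", call. = FALSE)

  if (any(!is.finite(data$phenotype)))
    stop("non-finite phenotype values", call. = FALSE)
  if (any(is.na(data$stdev) | data$stdev < 0))
    stop("negative or missing phenotype standard deviation", call. = FALSE)
  if (any(is.na(data$n) | data$n < 1L))
    stop("replicate count must be >= 1", call. = FALSE)

  structure(list(sites = sites, wildtype = wildtype, data = data),
            class = "gpmap")
}

#' @export
print.gpmap <- function(x, ...) {
  L <- length(x$sites)
  ns <- vapply(x$sites, length, 0L)
  cat("Genotype-phenotype map: ", nrow(x$data), " genotypes, ", L, " sites (",
      paste(ns, collapse = "x"), " states), wildtype ", x$wildtype, "\n",
      sep = "")
  print(utils::head(x$data, 4))
  if (nrow(x$data) > 4) cat("... ", nrow(x$data) - 4, " more rows\n")
  invisible(x)
}

#' Number of mutated sites in a map
#' @param map a [gpmap] object
#' @return integer site count
#' @export
n_sites <- function(map) length(map$sites)

is_binary_map <- function(map) {
  all(vapply(map$sites, length, 0L) == 2L)
}

#' Read a genotype-phenotype map file
#'
#' Two plain-text formats are supported. The JSON dialect is a top-level
#' object with fields `sites` (array of per-site state-label arrays),
#' `wildtype` (string) and `data` (array of records with fields `genotype`,
#' `phenotype`, `stdev`, `n`). CSV/TSV files carry the header columns
#' `genotype,phenotype,stdev,n` (the latter two optional); state labels and
#' the wild type are then inferred as for [gpmap()]. Decimal separator is
#' "."; files with locale comma decimals are rejected.
#'
#' @param path file path
#' @param format one of `"json"`, `"csv"`, `"tsv"`; default guesses from the
#'   file extension.
#' @param wildtype optional wild-type genotype string (CSV input with
#'   non-binary labels).
#' @return a validated [gpmap]
#' @export
read_map <- function(path, format = c("auto", "json", "csv", "tsv"),
                     wildtype = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", csv = "csv", tsv = "tsv",
                     txt = "csv",
                     stop("cannot guess map format from extension '", ext,
                          "'", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(obj$data) || is.null(obj$wildtype))
      stop("JSON map must have 'wildtype' and 'data' fields", call. = FALSE)
    recs <- obj$data
    df <- data.frame(
      genotype = vapply(recs, function(r) as.character(r$genotype), ""),
      phenotype = vapply(recs, function(r) as.numeric(r$phenotype), 0),
      stdev = vapply(recs, function(r)
        if (is.null(r$stdev)) 0 else as.numeric(r$stdev), 0),
      n = vapply(recs, function(r)
        if (is.null(r$n)) 1L else as.integer(r$n), 0L),
      stringsAsFactors = FALSE)
    sites <- if (is.null(obj$sites)) NULL else
      lapply(obj$sites, function(s) as.character(unlist(s)))
    gpmap(df, sites = sites, wildtype = as.character(obj$wildtype))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", strip.white = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("genotype", "phenotype") %in% names(df)))
      stop("map file must have header columns genotype,phenotype", call. = FALSE)
    num_rx <- "^[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?$"
    for (col in intersect(c("phenotype", "stdev", "n"), names(df))) {
      bad <- !grepl(num_rx, df[[col]])
      if (any(bad))
        stop("parse error in column '", col, "': value '",
             df[[col]][which(bad)[1]],
             "' is not a valid number (\".\" decimal separator required)",
             call. = FALSE)
      df[[col]] <- as.numeric(df[[col]])
    }
    gpmap(df, wildtype = wildtype)
  }
}

#' Write a genotype-phenotype map file
#'
#' JSON output round-trips bit-exactly through [read_map()] (phenotypes are
#' serialized at full IEEE precision).
#'
#' @param map a [gpmap]
#' @param path output file path
#' @param format `"json"`, `"csv"` or `"tsv"`
#' @return `path`, invisibly
#' @export
write_map <- function(map, path, format = c("json", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "gpmap"))
  if (format == "json") {
    obj <- list(
      sites = lapply(map$sites, identity),
      wildtype = jsonlite::unbox(map$wildtype),
      data = lapply(seq_len(nrow(map$data)), function(i) {
        r <- map$data[i, ]
        list(genotype = jsonlite::unbox(r$genotype),
             phenotype = jsonlite::unbox(r$phenotype),
             stdev = jsonlite::unbox(r$stdev),
             n = jsonlite::unbox(r$n))
      }))
    jsonlite::write_json(obj, path, digits = I(17), pretty = TRUE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(format(map$data, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
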