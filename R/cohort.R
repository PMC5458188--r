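#' Construct a case-control cohort
#'
#' The central data container: one row per subject with a binary phenotype
#' (1 = case, 0 = control), one integer genotype column per declared variant
#' (copies of the alternate allele, `NA` for failed calls) and any number of
#' binary covariate columns plus an optional continuous `age` column.
#'
#' @param subjects A data.frame with at least columns `id` and `phenotype`,
#'   plus one column per variant id and any covariate columns.
#' @param variants A list of [variant_def()] objects (possibly empty).
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, variants = list()) {
  stopifnot(is.data.frame(subjects))
  if (!all(c("id", "phenotype") %in% names(subjects))) {
    stop("subjects must have 'id' and 'phenotype' columns")
  }
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id)) stop("subject ids must be unique")
  ph <- subjects$phenotype
  if (!all(ph %in% c(0L, 1L))) {
    stop("phenotype must be 0 (control) or 1 (case); offending rows: ",
         paste(utils::head(which(!ph %in% c(0L, 1L)), 5L), collapse = ", "))
  }
  subjects$phenotype <- as.integer(ph)
  if (is.null(names(variants)) && length(variants)) {
    names(variants) <- vapply(variants, `[[`, character(1L), "id")
  }
  for (v in variants) {
    stopifnot(inherits(v, "variant_def"))
    if (!v$id %in% names(subjects)) {
      stop("declared variant '", v$id, "' has no genotype column")
    }
    g <- subjects[[v$id]]
    if (!all(is.na(g) | g %in% 0:2)) {
      stop("genotype calls for '", v$id, "' must be 0, 1, 2 or NA")
    }
    subjects[[v$id]] <- as.integer(g)
  }
  structure(list(subjects = subjects, variants = variants), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n1 <- sum(x$subjects$phenotype == 1L)
  n0 <- sum(x$subjects$phenotype == 0L)
  cat(sprintf("<cohort> %d cases / %d controls; %d variant(s): %s\n",
              n1, n0, length(x$variants),
              paste(names(x$variants), collapse = ", ")))
  extra <- setdiff(names(x$subjects), c("id", "phenotype", names(x$variants)))
  if (length(extra)) cat("  covariates:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Numbers of cases and controls in a cohort
#' @param x A [cohort()].
#' @return Named integer vector `c(cases = , controls = )`.
#' @export
cohort_sizes <- function(x) {
  stopifnot(inherits(x, "cohort"))
  c(cases = sum(x$subjects$phenotype == 1L),
    controls = sum(x$subjects$phenotype == 0L))
}

parse_genotype_token <- function(tok, variant, missing_token) {
  r <- variant$allele_ref
  a <- variant$allele_alt
  out <- rep(NA_integer_, length(tok))
  tok <- trimws(as.character(tok))
  out[tok %in% c("0", "1", "2")] <- as.integer(tok[tok %in% c("0", "1", "2")])
  two <- nchar(tok) == 2L & !tok %in% missing_token
  if (any(two, na.rm = TRUE)) {
    s1 <- substr(tok, 1L, 1L)
    s2 <- substr(tok, 2L, 2L)
    # unordered: "CT" and "TC" are the same call
    n_alt <- (s1 == a) + (s2 == a)
    ok <- two & ((s1 == r | s1 == a) & (s2 == r | s2 == a))
    out[which(ok)] <- as.integer(n_alt[which(ok)])
  }
  out
}

format_genotype_call <- function(calls, variant, missing_token = "NA") {
  lab <- genotype_class_labels(variant)
  out <- ifelse(is.na(calls), missing_token, lab[calls + 1L])
  out
}

#' Read a subject-level cohort table
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' unless `sep` is given) with one row per subject. Genotypes may be coded as
#' unordered two-character allele strings (`"CT"` is `"TC"`), as 0/1/2
#' alternate-allele counts, or as the declared missing token; any other token
#' becomes a missing call, never an error, so a stray genotyping artefact
#' cannot abort an analysis.
#'
#' @param path Path to the delimited file (one header row).
#' @param variants List of [variant_def()]s; genotype columns are located by
#'   variant id unless remapped in `schema$genotypes`.
#' @param schema Optional list of column mappings: `phenotype` (column name,
#'   default `"phenotype"`), `case`/`control` (labels coding the phenotype,
#'   default `"1"`/`"0"`), `id` (default `"id"`, synthesised if absent),
#'   `covariates` (character vector of covariate columns to keep; default all
#'   remaining columns), `genotypes` (named character vector variant id ->
#'   column name).
#' @param missing_token Token(s) denoting a missing genotype call
#'   (default `"NA"`).
#' @param sep Field separator; `NULL` (default) autodetects `,` vs tab.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, variants, schema = list(), missing_token = "NA",
                        sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0L))
  ph_col <- schema$phenotype %||% "phenotype"
  if (!ph_col %in% names(raw)) {
    stop("mandatory phenotype column '", ph_col, "' not found in ", path)
  }
  case_lab <- as.character(schema$case %||% "1")
  ctrl_lab <- as.character(schema$control %||% "0")
  ph_raw <- trimws(raw[[ph_col]])
  bad <- which(!ph_raw %in% c(case_lab, ctrl_lab))
  if (length(bad)) {
    stop("phenotype value '", ph_raw[bad[1L]], "' at row ", bad[1L],
         " is neither case label '", case_lab, "' nor control label '",
         ctrl_lab, "'")
  }
  id_col <- schema$id %||% "id"
  ids <- if (id_col %in% names(raw)) raw[[id_col]] else sprintf("S%04d", seq_len(nrow(raw)))
  subjects <- data.frame(id = ids,
                         phenotype = as.integer(ph_raw == case_lab),
                         stringsAsFactors = FALSE)
  gmap <- schema$genotypes
  for (v in variants) {
    col <- if (!is.null(gmap) && v$id %in% names(gmap)) gmap[[v$id]] else v$id
    if (!col %in% names(raw)) stop("genotype column '", col, "' not found for variant '", v$id, "'")
    subjects[[v$id]] <- parse_genotype_token(raw[[col]], v, missing_token)
  }
  cov_cols <- schema$covariates %||%
    setdiff(names(raw), c(ph_col, id_col,
                          vapply(variants, function(v) {
                            if (!is.null(gmap) && v$id %in% names(gmap)) gmap[[v$id]] else v$id
                          }, character(1L))))
  for (cc in cov_cols) {
    val <- trimws(raw[[cc]])
    val[val %in% missing_token] <- NA
    subjects[[cc]] <- suppressWarnings(as.numeric(val))
  }
  cohort(subjects, variants)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]: genotype calls are rendered as two-character
#' allele strings in reference/alternate orientation and missing calls as
#' `missing_token`, so `read_cohort(write_cohort(x))` is the identity.
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @param missing_token Token for missing genotype calls.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",", missing_token = "NA") {
  stopifnot(inherits(x, "cohort"))
  out <- x$subjects
  for (v in x$variants) {
    out[[v$id]] <- format_genotype_call(out[[v$id]], v, missing_token)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Tabulate genotype counts for one variant
#'
#' Counts subjects by phenotype and genotype class, silently dropping missing
#' calls at that variant (complete-case per variant, which is why per-variant
#' totals can sit below the cohort case/control totals).
#'
#' @param x A [cohort()].
#' @param variant_id Id of a declared variant.
#' @return A `genotype_count_table`: a 2x3 integer matrix, rows
#'   `case`/`control`, columns the genotype classes in copies-of-alternate
#'   order, with the variant attached as an attribute.
#' @export
genotype_counts <- function(x, variant_id) {
  stopifnot(inherits(x, "cohort"))
  if (!variant_id %in% names(x$variants)) {
    stop("unknown variant '", variant_id, "'")
  }
  v <- x$variants[[variant_id]]
  g <- x$subjects[[variant_id]]
  ph <- x$subjects$phenotype
  m <- matrix(0L, 2L, 3L,
              dimnames = list(c("case", "control"), genotype_class_labels(v)))
  keep <- !is.na(g)
  tab <- table(factor(ph[keep], levels = c(1L, 0L)),
               factor(g[keep], levels = 0:2))
  m[] <- as.integer(tab)
  structure(m, variant = v, class = c("genotype_count_table", "matrix", "array"))
}

#' Assemble a genotype count table directly from counts
#'
#' For working from published summary tables when the subject-level data are
#' not available.
#'
#' @param variant A [variant_def()].
#' @param cases,controls Length-3 integer vectors of genotype counts in
#'   copies-of-alternate order (0, 1, 2).
#' @return A `genotype_count_table`.
#' @export
genotype_count_table <- function(variant, cases, controls) {
  stopifnot(inherits(variant, "variant_def"),
            length(cases) == 3L, length(controls) == 3L,
            all(cases >= 0), all(controls >= 0))
  m <- matrix(as.integer(rbind(cases, controls)), 2L, 3L,
              dimnames = list(c("case", "control"),
                              genotype_class_labels(variant)))
  structure(m, variant = variant,
            class = c("genotype_count_table", "matrix", "array"))
}

#' A 2x2 exposure-by-phenotype count table
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @param exposed,unexposed Optional labels for the two exposure levels.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, exposed = "exposed", unexposed = "unexposed") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("2x2 cells must be non-negative")
  if (sum(cells) == 0) stop("2x2 table is empty")
  structure(list(a = a, b = b, c = c, d = d,
                 labels = c(exposed = exposed, unexposed = unexposed)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(c("case", "control"),
                              unname(x$labels[c("exposed", "unexposed")])))
  print(m)
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
         dimnames = list(c("case", "control"),
                         unname(x$labels[c("exposed", "unexposed")])))
}

#' Collapse a genotype count table to a 2x2 contrast
#'
#' Under the dominant model, carriers of at least one non-baseline allele are
#' exposed and the baseline homozygote unexposed; under the recessive model
#' only the homozygote opposite the baseline is exposed. Row totals are
#' conserved.
#'
#' @param counts A `genotype_count_table` (from [genotype_counts()] or
#'   [genotype_count_table()]).
#' @param model `"dominant"` or `"recessive"`.
#' @return A [two_by_two()].
#' @export
collapse_counts <- function(counts, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  stopifnot(inherits(counts, "genotype_count_table"))
  v <- attr(counts, "variant")
  # reorder columns to exposure-dose order 0,1,2
  m <- unclass(counts)
  if (v$reference_genotype == "alt_hom") m <- m[, 3:1]
  exposed_cols <- if (model == "dominant") 2:3 else 3L
  lab <- collapse_labels(v, model)
  two_by_two(a = sum(m[1L, exposed_cols]), b = sum(m[1L, -exposed_cols]),
             c = sum(m[2L, exposed_cols]), d = sum(m[2L, -exposed_cols]),
             exposed = unname(lab["exposed"]), unexposed = unname(lab["unexposed"]))
}

#' Cross-tabulate a binary covariate against phenotype
#'
#' @param x A [cohort()].
#' @param covariate Name of a binary covariate column.
#' @param on_missing `"exclude"` (default) drops subjects with a missing
#'   value; `"error"` aborts.
#' @return A [two_by_two()] with exposed = covariate value 1.
#' @export
crosstab_covariate <- function(x, covariate, on_missing = c("exclude", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(x, "cohort"))
  if (!covariate %in% names(x$subjects)) stop("covariate '", covariate, "' not found")
  val <- x$subjects[[covariate]]
  if (anyNA(val)) {
    if (on_missing == "error") stop("covariate '", covariate, "' has missing values")
    keep <- !is.na(val)
  } else keep <- rep(TRUE, length(val))
  if (!all(val[keep] %in% c(0, 1))) stop("covariate '", covariate, "' is not binary 0/1")
  ph <- x$subjects$phenotype[keep]
  val <- val[keep]
  two_by_two(a = sum(ph == 1L & val == 1), b = sum(ph == 1L & val == 0),
             c = sum(ph == 0L & val == 1), d = sum(ph == 0L & val == 0),
             exposed = paste0(covariate, "=1"), unexposed = paste0(covariate, "=0"))
}

#' Expand genotype count tables into a subject-level cohort
#'
#' Builds a cohort whose per-variant genotype counts reproduce the supplied
#' tables exactly. Within each phenotype group, genotype calls for different
#' variants are assigned in block order independently of one another, and
#' subjects beyond a variant's tabulated total get a missing call — adequate
#' for every single-variant statistic (which is complete-case per variant),
#' but carrying no information about between-variant phase or covariates.
#'
#' @param tables List of `genotype_count_table`s.
#' @param n_cases,n_controls Cohort totals; default the maximum per-phenotype
#'   table total.
#' @return A [cohort()].
#' @export
cohort_from_genotype_counts <- function(tables, n_cases = NULL, n_controls = NULL) {
  stopifnot(length(tables) >= 1L)
  case_tot <- max(vapply(tables, function(t) sum(unclass(t)[1L, ]), numeric(1L)))
  ctrl_tot <- max(vapply(tables, function(t) sum(unclass(t)[2L, ]), numeric(1L)))
  n_cases <- n_cases %||% case_tot
  n_controls <- n_controls %||% ctrl_tot
  subjects <- data.frame(
    id = sprintf("S%04d", seq_len(n_cases + n_controls)),
    phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
    stringsAsFactors = FALSE
  )
  variants <- lapply(tables, attr, "variant")
  names(variants) <- vapply(variants, `[[`, character(1L), "id")
  for (t in tables) {
    v <- attr(t, "variant")
    m <- unclass(t)
    calls_case <- rep(0:2, m[1L, ])
    calls_ctrl <- rep(0:2, m[2L, ])
    subjects[[v$id]] <- c(calls_case, rep(NA_integer_, n_cases - length(calls_case)),
                          calls_ctrl, rep(NA_integer_, n_controls - length(calls_ctrl)))
  }
  cohort(subjects, variants)
}

#' Read a column-mapping schema from YAML or JSON
#'
#' Convenience loader for the `schema` argument of [read_cohort()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_schema <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML schemas")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
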