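#' Define a biallelic variant
#'
#' A variant definition carries the two alleles and, crucially, an explicit
#' baseline genotype for odds-ratio contrasts. The baseline is never inferred
#' from allele frequency: in the motivating study the baseline homozygote for
#' rs73013281 (CC) is the *minor* homozygote, so frequency-based inference
#' would silently flip every contrast.
#'
#' Genotype calls are stored throughout the package as copies of `allele_alt`
#' (0, 1 or 2); the contrast orientation is derived from
#' `reference_genotype` at analysis time.
#'
#' @param id Variant identifier, e.g. `"rs73013281"`.
#' @param allele_ref Single-character reference allele.
#' @param allele_alt Single-character alternate allele.
#' @param reference_genotype Baseline homozygote for OR contrasts: either
#'   `"ref_hom"` (two copies of `allele_ref`, the default) or `"alt_hom"`.
#' @return An object of class `variant_def`.
#' @examples
#' variant_def("rs73013281", "C", "T")            # baseline CC
#' variant_def("rs167007", "A", "G", "alt_hom")   # baseline GG
#' @export
variant_def <- function(id, allele_ref, allele_alt,
                        reference_genotype = c("ref_hom", "alt_hom")) {
  reference_genotype <- match.arg(reference_genotype)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(nchar(allele_ref) == 1L, nchar(allele_alt) == 1L)
  if (identical(allele_ref, allele_alt)) {
    stop("allele_ref and allele_alt must differ for variant '", id, "'")
  }
  structure(
    list(id = id, allele_ref = allele_ref, allele_alt = allele_alt,
         reference_genotype = reference_genotype),
    class = "variant_def"
  )
}

#' @export
print.variant_def <- function(x, ...) {
  base <- if (x$reference_genotype == "ref_hom") {
    paste0(x$allele_ref, x$allele_ref)
  } else {
    paste0(x$allele_alt, x$allele_alt)
  }
  cat(sprintf("<variant_def> %s %s>%s (baseline %s)\n",
              x$id, x$allele_ref, x$allele_alt, base))
  invisible(x)
}

# Baseline genotype spelled out as a two-letter string, e.g. "CC".
reference_genotype_label <- function(variant) {
  a <- if (variant$reference_genotype == "ref_hom") variant$allele_ref else variant$allele_alt
  paste0(a, a)
}

# Copies of the *exposure* allele (the allele absent from the baseline
# homozygote), given calls coded as copies of allele_alt.
exposure_dose <- function(calls, variant) {
  if (variant$reference_genotype == "ref_hom") calls else 2L - calls
}

genotype_class_labels <- function(variant) {
  r <- variant$allele_ref
  a <- variant$allele_alt
  # indexed by copies of allele_alt: 0, 1, 2
  c(paste0(r, r), paste0(r, a), paste0(a, a))
}

#' Genetic model design-column builder
#'
#' Builds the design columns for a genetic coding from genotype calls,
#' oriented against the variant's declared baseline genotype. `codominant`
#' yields two indicator columns (heterozygote and non-baseline homozygote),
#' `dominant` and `recessive` one indicator, `additive` the 0/1/2 exposure
#' allele dose.
#'
#' @param name One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"additive"`.
#' @return An object of class `genetic_coding` holding the name and a
#'   `build(calls, variant)` function returning a named column matrix.
#' @export
genetic_coding <- function(name = c("codominant", "dominant", "recessive", "additive")) {
  name <- match.arg(name)
  build <- switch(name,
    codominant = function(calls, variant) {
      x <- exposure_dose(calls, variant)
      lab <- genotype_class_labels(variant)
      if (variant$reference_genotype == "alt_hom") lab <- rev(lab)
      m <- cbind(as.numeric(x == 1L), as.numeric(x == 2L))
      colnames(m) <- c(lab[2L], lab[3L])
      m
    },
    dominant = function(calls, variant) {
      m <- cbind(as.numeric(exposure_dose(calls, variant) >= 1L))
      colnames(m) <- paste0(collapse_labels(variant, "dominant")["exposed"])
      m
    },
    recessive = function(calls, variant) {
      m <- cbind(as.numeric(exposure_dose(calls, variant) == 2L))
      colnames(m) <- paste0(collapse_labels(variant, "recessive")["exposed"])
      m
    },
    additive = function(calls, variant) {
      m <- cbind(as.numeric(exposure_dose(calls, variant)))
      colnames(m) <- paste0(variant$id, "_dose")
      m
    }
  )
  structure(list(name = name, build = build), class = "genetic_coding")
}

as_genetic_coding <- function(coding) {
  if (inherits(coding, "genetic_coding")) coding else genetic_coding(coding)
}

# Human-readable labels for the collapsed 2-level contrast.
collapse_labels <- function(variant, model) {
  lab <- genotype_class_labels(variant) # by copies of alt
  if (variant$reference_genotype == "alt_hom") lab <- rev(lab) # by exposure dose
  if (model == "dominant") {
    c(exposed = paste(lab[2L], lab[3L], sep = "+"), unexposed = lab[1L])
  } else {
    c(exposed = lab[3L], unexposed = paste(lab[1L], lab[2L], sep = "+"))
  }
}
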