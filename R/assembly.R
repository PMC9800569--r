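#' Genome assembly model
#'
#' A `genome_assembly` holds, per chromosome, its total length and the
#' centromere interval. Both are needed to classify allelic imbalances:
#' telomeric AIs must not cross the centromere, and large-scale state
#' transitions are evaluated per chromosome arm.
#'
#' Bundled tables for hg19 and hg38 use the cytoband acen intervals as the
#' centromere model. By default the Y chromosome is dropped (the scar scores
#' were developed for female cancers); pass `chromosomes` to override.
#'
#' @param build one of `"hg19"`, `"hg38"`, or a path to a tab-delimited table
#'   with columns `chromosome`, `length_bp`, `centromere_start_bp`,
#'   `centromere_end_bp` (a custom assembly).
#' @param chromosomes optional character vector restricting (and ordering) the
#'   chromosome set. Default: all autosomes plus X, Y excluded.
#' @param include_y keep chrY when `chromosomes` is not given.
#' @return An object of class `genome_assembly`: a list with `build_label`
#'   and a data frame `chromosomes`.
#' @examples
#' asm <- genome_assembly("hg38")
#' head(asm$chromosomes)
#' @export
genome_assembly <- function(build = c("hg38", "hg19"), chromosomes = NULL,
                            include_y = FALSE) {
  if (length(build) > 1L) build <- build[[1L]]
  if (build %in% c("hg19", "hg38")) {
    path <- system.file("extdata", paste0("assembly_", build, ".tsv"),
                        package = "hrdscars", mustWork = TRUE)
    label <- build
  } else {
    if (!file.exists(build)) {
      stop("unknown build and no such assembly file: ", build)
    }
    path <- build
    label <- "custom"
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chromosome", "length_bp", "centromere_start_bp",
                "centromere_end_bp")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("assembly table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[, required]
  if (is.null(chromosomes) && !include_y) {
    tab <- tab[!tab$chromosome %in% c("chrY", "Y"), , drop = FALSE]
  }
  if (!is.null(chromosomes)) {
    missing_chr <- setdiff(chromosomes, tab$chromosome)
    if (length(missing_chr) > 0L) {
      stop("chromosome(s) not in assembly: ",
           paste(missing_chr, collapse = ", "))
    }
    tab <- tab[match(chromosomes, tab$chromosome), , drop = FALSE]
  }
  rownames(tab) <- NULL
  validate_assembly(tab)
  structure(list(build_label = label, chromosomes = tab),
            class = "genome_assembly")
}

#' Build a custom genome assembly from vectors
#'
#' Convenience constructor used by the simulator and by tests; all
#' coordinates are 1-based base pairs.
#'
#' @param chromosome character vector of chromosome names (unique).
#' @param length_bp,centromere_start_bp,centromere_end_bp integer vectors,
#'   one entry per chromosome.
#' @return A `genome_assembly` with `build_label = "custom"`.
#' @export
custom_assembly <- function(chromosome, length_bp, centromere_start_bp,
                            centromere_end_bp) {
  tab <- data.frame(chromosome = as.character(chromosome),
                    length_bp = as.numeric(length_bp),
                    centromere_start_bp = as.numeric(centromere_start_bp),
                    centromere_end_bp = as.numeric(centromere_end_bp),
                    stringsAsFactors = FALSE)
  validate_assembly(tab)
  structure(list(build_label = "custom", chromosomes = tab),
            class = "genome_assembly")
}

validate_assembly <- function(tab) {
  if (anyDuplicated(tab$chromosome)) {
    stop("duplicated chromosome names in assembly")
  }
  bad <- !(tab$centromere_start_bp > 0 &
             tab$centromere_start_bp < tab$centromere_end_bp &
             tab$centromere_end_bp < tab$length_bp)
  if (any(bad)) {
    stop("invalid centromere interval for chromosome(s): ",
         paste(tab$chromosome[bad], collapse = ", "))
  }
  invisible(tab)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> build=%s, %d chromosomes (%.0f Mb total)\n",
              x$build_label, nrow(x$chromosomes),
              sum(x$chromosomes$length_bp) / 1e6))
  invisible(x)
}

# Look up one chromosome's row; errors on unknown chromosome.
assembly_row <- function(assembly, chrom) {
  i <- match(chrom, assembly$chromosomes$chromosome)
  if (is.na(i)) stop("unknown chromosome in assembly: ", chrom)
  assembly$chromosomes[i, ]
}
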