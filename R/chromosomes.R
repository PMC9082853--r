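#' Chromosome length tables
#'
#' A chromosome set is the minimal genome description the trans model needs:
#' an ordered table of chromosome names and lengths in base pairs.
#'
#' @param name Character vector of unique chromosome labels.
#' @param length Integer-valued vector of chromosome lengths in base pairs,
#'   all positive, same length as `name`.
#'
#' @return A `data.frame` of class `"chromosome_set"` with columns `name`
#'   and `length`.
#' @seealso [grch38_chromosomes()], [read_chromosome_lengths()],
#'   [trans_model()]
#' @examples
#' chromosome_set(c("chrA", "chrB"), c(1e6, 2e6))
#' @export
chromosome_set <- function(name, length) {
  name <- as.character(name)
  length <- as.numeric(length)
  if (base::length(name) != base::length(length)) {
    stop("'name' and 'length' must have the same length")
  }
  if (base::length(name) == 0L) stop("chromosome set must be non-empty")
  if (anyDuplicated(name)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("all chromosome lengths must be positive and finite")
  }
  if (any(length != floor(length))) {
    stop("chromosome lengths must be whole numbers of base pairs")
  }
  structure(
    data.frame(name = name, length = length, stringsAsFactors = FALSE),
    class = c("chromosome_set", "data.frame")
  )
}

#' Default human chromosome lengths (GRCh38, chr1-22 + chrX)
#'
#' The 23 chromosomes over which the trans model is marginalized: the 22
#' autosomes plus chromosome X, with GRCh38 sequence lengths. Any recent
#' genome build gives results indistinguishable at the tolerances of this
#' analysis; the build in use is recorded in fit output metadata.
#'
#' @return A [chromosome_set()] with 23 rows.
#' @examples
#' sum(grch38_chromosomes()$length)  # ~3.03 Gb
#' @export
grch38_chromosomes <- function() {
  chromosome_set(
    name = c(paste0("chr", 1:22), "chrX"),
    length = c(
      248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
      159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
      114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
      58617616, 64444167, 46709983, 50818468, 156040895
    )
  )
}

#' Read chromosome lengths from a file
#'
#' Accepts either a headered two-column TSV (`name`, `length_bp`; extra
#' columns ignored) or a FASTA index (`.fai`) layout, i.e. a headerless TSV
#' whose first two columns are sequence name and length.
#'
#' @param path Path to the file.
#' @return A [chromosome_set()].
#' @export
read_chromosome_lengths <- function(path) {
  if (!file.exists(path)) stop("chromosome length file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  headered <- is.na(suppressWarnings(as.numeric(fields[2])))
  tab <- utils::read.delim(path, header = headered,
                           stringsAsFactors = FALSE)
  if (headered) {
    if (!all(c("name", "length_bp") %in% names(tab))) {
      stop("headered chromosome table must have columns 'name' and 'length_bp'")
    }
    chromosome_set(tab$name, tab$length_bp)
  } else {
    chromosome_set(tab[[1]], tab[[2]])
  }
}
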