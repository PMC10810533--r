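#' Genetic code tables for ORF calling and codon models
#'
#' Builds a genetic-code object from an NCBI translation-table id or from a
#' custom 64-line codon table. Ciliates use several codes: most classes
#' reassign TAA/TAG to glutamine (table 6, the ciliate/dasycladacean code),
#' while *Euplotes* reads TGA as cysteine (table 10). Stop-codon usage
#' therefore has to be a parameter of every codon-level computation in this
#' package, not a constant.
#'
#' @param code id accepted by [Biostrings::getGeneticCode()] (e.g. `1`, `6`,
#'   `10`), an existing `genetic_code` object (returned unchanged), or a path
#'   prefixed with `"custom:"` pointing to a tab-separated file with 64 lines
#'   `codon<TAB>aa-or-*`.
#' @return An object of class `genetic_code` with elements `id`, `map`
#'   (named character of length 64, `*` marks stops), `stop_codons`,
#'   `sense_codons`.
#' @examples
#' code6 <- genetic_code(6)
#' code6$map[c("TAA", "TAG", "TGA")]  # Q Q *
#' @export
genetic_code <- function(code = 1) {
  if (inherits(code, "genetic_code")) return(code)
  if (is.character(code) && startsWith(code, "custom:")) {
    path <- sub("^custom:", "", code)
    map <- read_custom_code(path)
    id <- paste0("custom:", basename(path))
  } else {
    map <- Biostrings::getGeneticCode(as.character(code))
    # keep only the 64 unambiguous codons, in a fixed order
    map <- map[all_codons()]
    id <- as.character(code)
  }
  structure(list(
    id = id,
    map = map,
    stop_codons = names(map)[map == "*"],
    sense_codons = names(map)[map != "*"]
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code", x$id, "-", length(x$sense_codons), "sense codons, stops:",
      paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

all_codons <- function() {
  nt <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

read_custom_code <- function(path) {
  if (!file.exists(path)) stop("custom genetic code file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("codon", "aa"),
                           colClasses = "character", strip.white = TRUE)
  tab$codon <- toupper(gsub("U", "T", tab$codon))
  if (nrow(tab) != 64 || anyDuplicated(tab$codon) ||
      !setequal(tab$codon, all_codons())) {
    stop("custom code file must contain each of the 64 codons exactly once")
  }
  bad <- !grepl("^[A-Z*]$", tab$aa)
  if (any(bad)) stop("invalid amino-acid symbol in custom code: ",
                     paste(unique(tab$aa[bad]), collapse = ", "))
  map <- stats::setNames(tab$aa, tab$codon)
  map[all_codons()]
}

#' Translate in-frame nucleotide sequence under a genetic code
#'
#' Codons containing any non-ACGT symbol translate to `"X"`; ambiguity is
#' never resolved optimistically.
#'
#' @param cds character scalar, length divisible by 3.
#' @param code a [genetic_code()] or id.
#' @return character scalar protein (may contain `*` for stops and `X`).
#' @export
translate_cds <- function(cds, code = 1) {
  code <- genetic_code(code)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3: ", n)
  if (n == 0L) return("")
  cod <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(code$map[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Degeneracy classes of the code: amino acids grouped by number of
# synonymous sense codons. Used by Wright's ENc, whose N_k terms depend on
# the active code (e.g. Gln is 4-fold under table 6).
degeneracy_classes <- function(code) {
  code <- genetic_code(code)
  sense <- code$map[code$map != "*"]
  split(names(table(sense)), as.integer(table(sense)))
}

# Four-fold degenerate codon "boxes": first-two-nucleotide boxes whose four
# third-position variants are all sense and synonymous. GC3s is computed on
# codons from these boxes only.
fourfold_boxes <- function(code) {
  code <- genetic_code(code)
  boxes <- unique(substr(all_codons(), 1L, 2L))
  keep <- vapply(boxes, function(b) {
    aas <- code$map[paste0(b, c("T", "C", "A", "G"))]
    !any(aas == "*") && length(unique(aas)) == 1L
  }, logical(1))
  boxes[keep]
}
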