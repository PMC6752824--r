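#' Ranked list
#'
#' An ordered list of distinct labels, e.g. cancers ordered by PageRank or
#' by estimated deaths.  Labels are canonicalised (see
#' [canonicalize_cancer_label]) before the duplicate check so that overlap
#' counts never hinge on silent string-form differences.
#'
#' @param items character vector, best first.
#' @param name provenance tag.
#' @param canonicalize apply the cancer-label canonicalisation table.
#' @return object of class `ranked_list`.
#' @export
ranked_list <- function(items, name = "ranked list", canonicalize = TRUE) {
  items <- as.character(items)
  if (length(items) == 0L) stop("ranked list must be non-empty")
  if (canonicalize) items <- canonicalize_cancer_label(items)
  dup <- items[duplicated(items)]
  if (length(dup)) {
    stop("duplicate label(s) after normalization in '", name, "': ",
         paste(unique(dup), collapse = ", "))
  }
  structure(list(name = name, items = items), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat("Ranked list '", x$name, "' (", length(x$items), " items)\n",
      sep = "")
  top <- utils::head(x$items, n)
  cat(paste0(" ", seq_along(top), ". ", top, collapse = "\n"), "\n")
  invisible(x)
}

# explicit, versioned canonicalisation table (v1).  The published tables
# vary word forms ("Hodgkin's" vs "Hodgkin", abbreviations NETs, GTD, short
# forms without the "cancer"/"tumor" noun).  Melanoma and Skin cancer are
# distinct entries and are never merged.
cancer_label_canon_v1 <- c(
  "Hodgkin's lymphoma" = "Hodgkin lymphoma",
  "Hodgkin’s lymphoma" = "Hodgkin lymphoma",
  "Hodgkin's" = "Hodgkin lymphoma",
  "Hodgkin" = "Hodgkin lymphoma",
  "Non-Hodgkin's lymphoma" = "Non-Hodgkin lymphoma",
  "Non-Hodgkin’s lymphoma" = "Non-Hodgkin lymphoma",
  "Non-Hodgkin" = "Non-Hodgkin lymphoma",
  "M. myeloma" = "Multiple myeloma",
  "NETs" = "Neuroendocrine tumor",
  "Neuroendocrine tumors" = "Neuroendocrine tumor",
  "GTD" = "Gestational trophoblastic disease",
  "Cholangio." = "Cholangiocarcinoma",
  "Cholangio" = "Cholangiocarcinoma",
  "Head & Neck" = "Head and neck cancer",
  "Head and neck" = "Head and neck cancer",
  "Lung" = "Lung cancer",
  "Breast" = "Breast cancer",
  "Prostate" = "Prostate cancer",
  "Colorectal" = "Colorectal cancer",
  "Brain" = "Brain tumor",
  "Pancreatic" = "Pancreatic cancer",
  "Stomach" = "Stomach cancer",
  "Ovarian" = "Ovarian cancer",
  "Cervical" = "Cervical cancer",
  "Skin" = "Skin cancer",
  "Esophageal" = "Esophageal cancer",
  "Liver" = "Liver cancer",
  "Bladder" = "Bladder cancer",
  "Testicular" = "Testicular cancer",
  "Thyroid" = "Thyroid cancer",
  "Bone" = "Bone tumor",
  "Kidney" = "Kidney cancer",
  "Oral" = "Oral cancer",
  "Uterine" = "Uterine cancer",
  "Soft-tissue" = "Soft-tissue sarcoma",
  "Anal" = "Anal cancer",
  "Spinal" = "Spinal tumor",
  "Gallbladder" = "Gallbladder cancer",
  "Vaginal" = "Vaginal cancer",
  "Vulvar" = "Vulvar cancer",
  "Adrenal" = "Adrenal tumor",
  "Appendix" = "Appendix cancer")

#' Canonicalise cancer-type labels
#'
#' Maps the word-form variants and abbreviations occurring across the
#' shipped tables ("Hodgkin's lymphoma", "M. myeloma", "NETs", "GTD", short
#' forms like "Lung") onto a single canonical spelling per cancer type.
#' Unknown labels pass through unchanged (trimmed).  "Melanoma" and
#' "Skin cancer" remain distinct.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
canonicalize_cancer_label <- function(x) {
  x <- trimws(x)
  hit <- x %in% names(cancer_label_canon_v1)
  x[hit] <- unname(cancer_label_canon_v1[x[hit]])
  x
}

#' Top-j overlap curve of two ranked lists
#'
#' eta(j) = number of items common to the top j of both lists, for
#' j = 1..j_max.  eta is symmetric in its arguments, non-decreasing, and
#' grows by at most 2 per step (each list contributes one new item).
#'
#' @param a,b `ranked_list` objects (or character vectors, canonicalised).
#' @param j_max largest j; defaults to the shorter list length.
#' @return object of class `overlap_curve`: data.frame with columns `j`,
#'   `eta`, `percent`; attribute `pair`.
#' @export
overlap_curve <- function(a, b, j_max = NULL) {
  if (!inherits(a, "ranked_list")) a <- ranked_list(a, deparse(substitute(a)))
  if (!inherits(b, "ranked_list")) b <- ranked_list(b, deparse(substitute(b)))
  if (is.null(j_max)) j_max <- min(length(a$items), length(b$items))
  if (j_max > min(length(a$items), length(b$items))) {
    stop("j_max exceeds the shorter list length")
  }
  eta <- vapply(seq_len(j_max), function(j) {
    length(intersect(a$items[seq_len(j)], b$items[seq_len(j)]))
  }, integer(1L))
  out <- data.frame(j = seq_len(j_max), eta = eta,
                    percent = 100 * eta / seq_len(j_max))
  attr(out, "pair") <- c(a$name, b$name)
  class(out) <- c("overlap_curve", "data.frame")
  out
}

#' Write an overlap curve as TSV
#'
#' @param oc an `overlap_curve`.
#' @param path output file (`j<TAB>eta<TAB>percent`).
#' @export
write_overlap <- function(oc, path) {
  lines <- paste(oc$j, oc$eta, formatC(oc$percent, format = "f", digits = 2),
                 sep = "\t")
  writeLines(c("j\teta\tpercent", lines), path, useBytes = TRUE)
  invisible(path)
}

fixture_files <- c(
  table1 = "table1_cancers.tsv",
  table2 = "table2_drugs.tsv",
  table3 = "table3_pagerank.tsv",
  table4a = "table4a_gbd_deaths.tsv",
  table4b = "table4b_gbd_dalys.tsv",
  table5a = "table5a_globocan_deaths.tsv",
  table5b = "table5b_globocan_newcases.tsv")

#' Load a packaged ranking fixture
#'
#' Transcriptions of the published tables ship with the package:
#' `table1` (37 cancer types, alphabetical), `table2` (203 cancer drugs,
#' alphabetical), `table3` (240 cancers+drugs in Wikipedia PageRank order,
#' with category and per-category sub-index), `table4a`/`table4b` (GBD-2017
#' cancer rankings by deaths / DALYs), `table5a`/`table5b` (GLOBOCAN-2018
#' rankings by deaths / new cases).  Derived views: `wiki_cancers` (the
#' cancers-only sub-order of table3) and `wiki_drugs` (drugs-only).
#'
#' @param name fixture identifier (see above).
#' @return a `ranked_list`; for `table3` the full data.frame is attached as
#'   attribute `table`.
#' @export
load_fixture <- function(name) {
  if (name %in% c("wiki_cancers", "wiki_drugs")) {
    t3 <- fixture_table("table3")
    want <- if (name == "wiki_cancers") "cancer" else "drug"
    rl <- ranked_list(t3$label[t3$category == want], name)
    return(rl)
  }
  if (!name %in% names(fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(c(names(fixture_files), "wiki_cancers", "wiki_drugs"),
               collapse = ", "))
  }
  df <- fixture_table(name)
  rl <- ranked_list(df$label, name,
                    canonicalize = !name %in% c("table2", "table3"))
  attr(rl, "table") <- df
  rl
}

fixture_table <- function(name) {
  path <- system.file("extdata", fixture_files[[name]], package = "regomax",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
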