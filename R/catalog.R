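#' Built-in EPS/LPS gene catalog
#'
#' The 12 proteins involved in exopolysaccharide (EPS) and
#' lipopolysaccharide (LPS) biosynthesis and export that the pipeline
#' profiles, with their KEGG Orthology (KO) numbers and the TIGRFAMs /
#' Pfam profile-HMM identifiers used to detect them in translated read
#' fragments. Two of the LPS-transport genes (\emph{lptC}, \emph{lptG})
#' are covered by two HMMs each.
#'
#' @return A data.frame with one row per gene and columns
#'   \code{gene}, \code{ko}, \code{hmm_ids} (comma-separated HMM
#'   identifiers), and \code{class} (\code{"EPS"} or \code{"LPS"}).
#' @seealso [load_catalog()] to read a custom catalog from file.
#' @export
#' @examples
#' cat12 <- eps_lps_catalog()
#' nrow(cat12)                       # 12
#' subset(cat12, gene == "wza")$ko   # "K01991"
eps_lps_catalog <- function() {
  df <- data.frame(
    gene = c("wza", "wcaB", "wcaF", "wcaK/amsJ", "kpsE", "algE",
             "algJ", "sacB", "wzt", "lptC", "lptF", "lptG"),
    ko = c("K01991", "K03819", "K03818", "K16710", "K10107", "K16081",
           "K19295", "K00692", "K09691", "K11719", "K07091", "K11720"),
    hmm_ids = c("PF02563", "TIGR04016", "TIGR04008", "TIGR04006",
                "TIGR01010", "PF13372", "PF16822", "PF02435",
                "PF14524", "TIGR04409,PF06835", "TIGR04407",
                "TIGR04408,PF03739"),
    class = c(rep("EPS", 8L), rep("LPS", 4L)),
    stringsAsFactors = FALSE
  )
  validate_catalog(df)
}

#' Load a gene catalog
#'
#' Without a path, returns the built-in 12-gene EPS/LPS catalog
#' ([eps_lps_catalog()]). With a path, reads a tab-separated catalog
#' table with columns \code{gene}, \code{ko}, \code{hmm_ids}
#' (comma-separated) and \code{class}, and validates it.
#'
#' @param path Optional path to a tab-separated catalog file.
#' @return A validated catalog data.frame.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) return(eps_lps_catalog())
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "ko", "hmm_ids", "class")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("catalog file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_catalog(df[needed])
}

validate_catalog <- function(df) {
  if (nrow(df) == 0L) stop("catalog is empty")
  if (anyDuplicated(df$ko)) {
    stop("duplicate ko_id in catalog: ",
         paste(unique(df$ko[duplicated(df$ko)]), collapse = ", "))
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene name in catalog: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  if (any(!nzchar(trimws(df$hmm_ids))) || anyNA(df$hmm_ids)) {
    stop("catalog entries with empty hmm_ids: ",
         paste(df$gene[!nzchar(trimws(df$hmm_ids))], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Long-format HMM-to-KO map of a catalog
#'
#' Expands the comma-separated \code{hmm_ids} column into one row per
#' HMM identifier, the form used when matching HMM hits.
#'
#' @param catalog A catalog data.frame (see [load_catalog()]).
#' @return data.frame with columns \code{hmm_id}, \code{ko}, \code{gene}.
#' @export
catalog_hmm_map <- function(catalog) {
  ids <- strsplit(catalog$hmm_ids, ",", fixed = TRUE)
  n <- lengths(ids)
  data.frame(
    hmm_id = trimws(unlist(ids)),
    ko = rep(catalog$ko, n),
    gene = rep(catalog$gene, n),
    stringsAsFactors = FALSE
  )
}
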