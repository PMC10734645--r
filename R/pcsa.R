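# Physiological cross-sectional areas (PCSA) and their group arithmetic.
#
# Three literature sources give per-muscle areas; a fourth (Pierrynowski) is
# available only as grouped sums. One printed value (obturator externus,
# Brand column: 3795) is a suspected decimal-typo artifact; it is stored as
# printed with a correction flag rather than silently fixed.

#' Per-muscle PCSA table
#'
#' @param source `"lube"`, `"brand"` or `"klein_horsmann"`; `NULL` returns
#'   all sources.
#' @param correct_typos replace flagged suspected-typo entries by their
#'   corrected value (default `TRUE`); set `FALSE` for the values exactly as
#'   printed.
#' @return Data frame with columns `source`, `muscle`, `pcsa_cm2`,
#'   `suspected_typo`.
#' @examples
#' pcsa_table("lube")
#' @export
pcsa_table <- function(source = NULL, correct_typos = TRUE) {
  tab <- utils::read.csv(.extdata("pcsa.csv"), stringsAsFactors = FALSE)
  if (correct_typos) {
    fix <- tab$suspected_typo & !is.na(tab$corrected_cm2)
    tab$pcsa_cm2[fix] <- tab$corrected_cm2[fix]
  }
  tab$corrected_cm2 <- NULL
  if (!is.null(source)) {
    source <- match.arg(source, c("lube", "brand", "klein_horsmann"))
    tab <- tab[tab$source == source, , drop = FALSE]
  }
  if (any(tab$pcsa_cm2 <= 0)) stop("PCSA values must be positive", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Members of the PCSA muscle groups
#'
#' Group A collects the proximally directed muscles (gluteus maximus, medius
#' and minimus, tensor fasciae latae); group B the external rotators
#' (piriformis, triceps coxae, obturator externus, quadratus femoris). The
#' fourth group-B member is implemented as obturator externus: that is the
#' reading consistent with the published per-muscle areas, although the
#' grouped table's caption names the internus.
#'
#' @param group `"A_proximal"` or `"B_rotators"`.
#' @return Character vector of muscle names.
#' @export
pcsa_group_members <- function(group = c("A_proximal", "B_rotators")) {
  group <- match.arg(group)
  switch(group,
         A_proximal = c("gluteus_maximus", "gluteus_medius",
                        "gluteus_minimus", "tensor_fasciae_latae"),
         B_rotators = c("piriformis", "triceps_coxae",
                        "obturator_externus", "quadratus_femoris"))
}

#' Grouped PCSA sum
#'
#' Arithmetic sum of the group members' areas in a single-source PCSA table.
#'
#' @param table a single-source [pcsa_table()] (columns `muscle`,
#'   `pcsa_cm2`).
#' @param group `"A_proximal"` or `"B_rotators"`.
#' @return Sum in cm^2.
#' @examples
#' pcsa_group_sum(pcsa_table("lube"), "A_proximal")  # 99.7
#' @export
pcsa_group_sum <- function(table, group = c("A_proximal", "B_rotators")) {
  group <- match.arg(group)
  members <- pcsa_group_members(group)
  if (!is.data.frame(table) || !all(c("muscle", "pcsa_cm2") %in% names(table))) {
    stop("'table' must be a PCSA data frame with muscle and pcsa_cm2", call. = FALSE)
  }
  missing <- setdiff(members, table$muscle)
  if (length(missing)) {
    stop("PCSA table lacks group member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(table$pcsa_cm2[match(members, table$muscle)])
}

#' PCSA group ratio
#'
#' The rotator-to-proximal area ratio `100 * b_sum / a_sum`, reported to one
#' decimal place.
#'
#' @param a_sum group-A (proximal) area sum, cm^2, > 0.
#' @param b_sum group-B (rotator) area sum, cm^2.
#' @return Percentage, rounded to one decimal.
#' @examples
#' pcsa_group_ratio(127.2, 52.4)  # 41.2
#' @export
pcsa_group_ratio <- function(a_sum, b_sum) {
  if (!is.numeric(a_sum) || a_sum <= 0) {
    stop("a_sum must be positive", call. = FALSE)
  }
  round(100 * b_sum / a_sum, 1L)
}

#' Published grouped PCSA sums and ratios
#'
#' The grouped sums (A, B) and printed ratios of the four literature sources,
#' including Pierrynowski, for which no per-muscle areas are available. The
#' `ratio_recomputed_pct` column is `100 * B / A` from the printed sums; for
#' three of the four sources it deviates from the printed ratio (the
#' published derivation is unknown), so both are reported.
#'
#' @return Data frame with columns `source`, `a_cm2`, `b_cm2`,
#'   `ratio_printed_pct`, `ratio_recomputed_pct`.
#' @export
pcsa_reference_groups <- function() {
  tab <- utils::read.csv(.extdata("pcsa_groups.csv"), stringsAsFactors = FALSE)
  tab$ratio_recomputed_pct <- vapply(seq_len(nrow(tab)), function(i) {
    pcsa_group_ratio(tab$a_cm2[i], tab$b_cm2[i])
  }, numeric(1L))
  tab
}
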