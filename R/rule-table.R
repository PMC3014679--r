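#' Fuzzy-PI rule tables
#'
#' The 7 x 7 Mamdani rule base mapping (error term, change-of-error term) to a
#' pump speed-variation term. The `"original"` table is the canonical
#' saturated-sum base: with terms indexed NL = -3 ... PL = +3, the consequent
#' of cell (i, j) is the term with index `clip(i + j, -3, 3)`. The `"tuned"`
#' table differs in exactly six cells that soften the control action when the
#' bulk is warm but already cooling -- (PL,NL), (PL,NM), (PL,NS) all become NS
#' -- and damp oscillation when the error is small but rising fast:
#' (PS,PL) = PM, (NS,PL) = PS, (NM,PL) = ZR.
#'
#' @param name `"tuned"` (default) or `"original"`.
#' @return A 7 x 7 character matrix of class `rule_table`; rows are error
#'   terms NL ... PL, columns change-of-error terms NL ... PL.
#' @export
#' @examples
#' rule_table("original")["ZR", "PS"]   # "PS"
#' tidy(rule_table("tuned"))
rule_table <- function(name = c("tuned", "original")) {
  name <- match.arg(name)
  idx <- outer(-3:3, -3:3, function(i, j) pmin(pmax(i + j, -3L), 3L))
  tab <- matrix(index_term(idx), 7L, 7L,
                dimnames = list(error = fuzzy_terms(), change_of_error = fuzzy_terms()))
  if (name == "tuned") {
    tab["PL", c("NL", "NM", "NS")] <- "NS"
    tab["PS", "PL"] <- "PM"
    tab["NS", "PL"] <- "PS"
    tab["NM", "PL"] <- "ZR"
  }
  structure(tab, class = c("rule_table", class(tab)), name = name)
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule table '%s'>\n", attr(x, "name")))
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a rule table into long form
#'
#' @param x A [rule_table()].
#' @param ... Unused.
#' @return A tibble with 49 rows: `error`, `change_of_error`, `speed_variation`.
#' @export
tidy.rule_table <- function(x, ...) {
  tidyr::expand_grid(error = fuzzy_terms(), change_of_error = fuzzy_terms()) |>
    mutate(speed_variation = purrr::map2_chr(.data$error, .data$change_of_error,
                                             ~ x[.x, .y]))
}
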