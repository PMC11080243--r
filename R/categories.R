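#' Interaction category space
#'
#' The ordered set of interaction categories that label edges of a PPI
#' network.  The default space is the seven STRING action modes in their
#' conventional order: Reaction, Binding, Ptmod (post-translational
#' modification), Activation, Inhibition, Catalysis, Expression.  A pair
#' of proteins may carry several categories at once, so edge labels are
#' multi-label binary vectors over this space.
#'
#' @param names Character vector of unique, non-empty category labels.
#' @return An object of class `category_space` with fields `names` and
#'   `t` (number of categories).
#' @examples
#' cs <- category_space()
#' cs$t        # 7
#' cs$names[1] # "Reaction"
#' @export
category_space <- function(names = c("Reaction", "Binding", "Ptmod",
                                     "Activation", "Inhibition",
                                     "Catalysis", "Expression")) {
  names <- as.character(names)
  if (length(names) < 1L || anyNA(names) || any(!nzchar(names)))
    stop("category names must be non-empty strings")
  if (anyDuplicated(tolower(names)))
    stop("category names must be unique (case-insensitively)")
  structure(list(names = names, t = length(names)),
            class = "category_space")
}

#' @export
print.category_space <- function(x, ...) {
  cat("<category_space> t =", x$t, "\n ", paste(x$names, collapse = ", "),
      "\n")
  invisible(x)
}

# Map free-text mode strings onto category indices, case-insensitively.
# Unknown modes return NA; callers decide whether that is an error.
match_category <- function(modes, categories) {
  match(tolower(trimws(modes)), tolower(categories$names))
}
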