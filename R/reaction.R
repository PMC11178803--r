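# Reaction records: one row of an HTE table, a role -> SMILES map plus yield.

#' Default role order for Buchwald-Hartwig-style tables
#'
#' Concatenation-based featurizers are order-sensitive, so the role order is
#' fixed once per table. The default mirrors the conventional
#' aryl halide / ligand / base / additive decomposition of C-N coupling HTE
#' screens.
#' @export
default_roles <- function() c("aryl_halide", "ligand", "base", "additive")

#' Construct a reaction record
#'
#' @param components named character vector or list, role -> SMILES.
#' @param yield numeric yield in [0, 100], or NA for prediction-only inputs.
#' @param id opaque identifier.
#' @param validate check that every SMILES parses (default TRUE).
#' @return an object of class \code{reaction}.
#' @export
reaction <- function(components, yield = NA_real_, id = NULL, validate = TRUE) {
  components <- unlist(components)
  stopifnot(is.character(components), !is.null(names(components)),
            all(nzchar(names(components))))
  if (!is.na(yield)) {
    if (!is.finite(yield) || yield < 0 || yield > 100)
      stop("yield must be finite and in [0, 100], got ", yield, call. = FALSE)
  }
  if (validate) {
    for (role in names(components)) {
      if (!smiles_parses(components[[role]]))
        stop("reaction ", if (is.null(id)) "<unnamed>" else id,
             ": SMILES for role '", role, "' failed to parse: '",
             components[[role]], "'", call. = FALSE)
    }
  }
  structure(list(components = components, yield = as.numeric(yield),
                 id = if (is.null(id)) NA_character_ else as.character(id)),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction", if (!is.na(x$id)) paste0(" ", x$id), "> yield=",
      format(x$yield), "\n", sep = "")
  for (role in names(x$components))
    cat("  ", format(role, width = 12), x$components[[role]], "\n")
  invisible(x)
}

#' Extract yields from a list of reactions
#' @param reactions list of \code{reaction} objects.
#' @return numeric vector.
#' @export
reaction_yields <- function(reactions) {
  vapply(reactions, function(r) r$yield, numeric(1))
}

#' Role set of a reaction list
#' @param reactions list of \code{reaction} objects.
#' @return character vector of roles (from the first reaction; the role set
#'   is fixed per table).
#' @export
reaction_roles <- function(reactions) {
  stopifnot(length(reactions) >= 1)
  names(reactions[[1]]$components)
}

#' Convert a reaction list to a data.frame
#' @param reactions list of \code{reaction} objects.
#' @return data.frame with one column per role plus \code{yield} and \code{id}.
#' @export
reactions_to_df <- function(reactions) {
  roles <- reaction_roles(reactions)
  cols <- lapply(roles, function(role)
    vapply(reactions, function(r) unname(r$components[[role]]), character(1)))
  names(cols) <- roles
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  df$yield <- reaction_yields(reactions)
  df$id <- vapply(reactions, function(r) r$id, character(1))
  df
}
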