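# Reaction-table I/O. The synthetic generator emits the same schema the
# loader consumes, so synthetic and real tables are interchangeable.

#' Reaction-table schema
#' @param roles named character vector: role -> CSV column name. Default
#'   maps each default role to a column of the same name.
#' @param yield_col yield column name (default "yield").
#' @param id_col optional id column name.
#' @return list of class \code{table_schema}.
#' @export
table_schema <- function(roles = stats::setNames(default_roles(),
                                                 default_roles()),
                         yield_col = "yield", id_col = "id") {
  structure(list(roles = roles, yield_col = yield_col, id_col = id_col),
            class = "table_schema")
}

#' Read a reaction table from CSV
#'
#' @param path CSV file with a header row.
#' @param schema a \code{table_schema}.
#' @param prediction_mode admit rows with missing yield (default FALSE).
#' @return list of \code{reaction} objects; SMILES are validated at load
#'   with row-level error reporting.
#' @export
read_reaction_csv <- function(path, schema = table_schema(),
                              prediction_mode = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(unname(schema$roles), schema$yield_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  yields <- suppressWarnings(as.numeric(df[[schema$yield_col]]))
  has_id <- !is.null(schema$id_col) && schema$id_col %in% names(df)
  lapply(seq_len(nrow(df)), function(i) {
    y <- yields[i]
    if (is.na(y) && !prediction_mode)
      stop("row ", i, ": missing or non-numeric yield", call. = FALSE)
    comps <- vapply(names(schema$roles),
                    function(role) as.character(df[[schema$roles[[role]]]][i]),
                    character(1))
    tryCatch(
      reaction(comps, yield = y,
               id = if (has_id) df[[schema$id_col]][i] else paste0("row", i)),
      error = function(e)
        stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Write a reaction table to CSV
#' @param reactions list of \code{reaction} objects.
#' @param path output file.
#' @param schema a \code{table_schema} (controls column names).
#' @return the path, invisibly.
#' @export
write_reaction_csv <- function(reactions, path, schema = table_schema()) {
  df <- reactions_to_df(reactions)
  roles <- reaction_roles(reactions)
  names(df)[match(roles, names(df))] <- unname(schema$roles[roles])
  names(df)[names(df) == "yield"] <- schema$yield_col
  if (!is.null(schema$id_col)) names(df)[names(df) == "id"] <- schema$id_col
  # full double precision so tables round-trip bit-exactly
  yc <- schema$yield_col
  df[[yc]] <- vapply(df[[yc]], function(v)
    if (is.na(v)) "" else format(v, digits = 17, trim = TRUE), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest beside an output
#' @param path manifest path.
#' @param config named list of settings (seeds included) sufficient to rerun
#'   the command.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config) {
  config$r_version <- as.character(getRversion())
  config$package_version <- as.character(utils::packageVersion("dklgp"))
  config$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
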