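#' Define the stimulus set for an implicit association test
#'
#' An IAT instrument contrasts two *concept* categories (e.g. silhouettes of
#' overweight vs. normal-weight individuals) against two *attribute*
#' categories (e.g. positively vs. negatively connoted words). This
#' constructor bundles the four category names and their item lists and
#' validates them. Concept items may be words or image identifiers; the
#' engine is headless and treats them as opaque labels.
#'
#' By convention the first attribute category is the positively valenced one
#' and the first concept category is "concept 1": the sign of a D score
#' ([compute_d()]) is oriented so that positive values indicate an implicit
#' preference for concept 1.
#'
#' @param attribute_names character vector of exactly two attribute category
#'   labels, positive-valence category first.
#' @param concept_names character vector of exactly two concept category
#'   labels.
#' @param attribute_items list of two non-empty character vectors, the word
#'   stimuli of each attribute category (same order as `attribute_names`).
#' @param concept_items list of two non-empty character vectors, the word or
#'   image-identifier stimuli of each concept category.
#' @return An object of class `iat_stimuli`.
#' @examples
#' stim <- iat_stimuli(
#'   attribute_names = c("good", "bad"),
#'   concept_names   = c("overweight", "normal weight"),
#'   attribute_items = list(c("joy", "love", "peace"), c("agony", "hurt", "evil")),
#'   concept_items   = list(c("ow1.png", "ow2.png"), c("nw1.png", "nw2.png"))
#' )
#' stim
#' @seealso [read_stimuli()] to load a set from a JSON or YAML config file.
#' @export
iat_stimuli <- function(attribute_names, concept_names,
                        attribute_items, concept_items) {
  check_pair <- function(x, what) {
    if (!is.character(x) || length(x) != 2L || anyNA(x) || any(!nzchar(x)))
      stop_validation(sprintf("exactly two non-empty %s category names are required", what))
    if (x[1L] == x[2L])
      stop_validation(sprintf("the two %s category names must differ", what))
  }
  check_items <- function(items, names, what) {
    if (!is.list(items) || length(items) != 2L)
      stop_validation(sprintf("%s_items must be a list of two character vectors", what))
    for (i in 1:2) {
      v <- items[[i]]
      if (!is.character(v) || length(v) == 0L || anyNA(v) || any(!nzchar(v)))
        stop_validation(sprintf("item list for %s category '%s' must be a non-empty character vector",
                                what, names[i]))
      if (anyDuplicated(v))
        stop_validation(sprintf("items must be unique within %s category '%s'", what, names[i]))
    }
  }
  check_pair(attribute_names, "attribute")
  check_pair(concept_names, "concept")
  check_items(attribute_items, attribute_names, "attribute")
  check_items(concept_items, concept_names, "concept")
  structure(
    list(
      attribute_names = unname(attribute_names),
      concept_names   = unname(concept_names),
      attribute_items = unname(lapply(attribute_items, unname)),
      concept_items   = unname(lapply(concept_items, unname))
    ),
    class = "iat_stimuli"
  )
}

#' @export
print.iat_stimuli <- function(x, ...) {
  cat("IAT stimulus set\n")
  for (i in 1:2)
    cat(sprintf("  attribute %d: %-14s (%d items)\n", i,
                x$attribute_names[i], length(x$attribute_items[[i]])))
  for (i in 1:2)
    cat(sprintf("  concept   %d: %-14s (%d items)\n", i,
                x$concept_names[i], length(x$concept_items[[i]])))
  invisible(x)
}

#' Read a stimulus set from a JSON or YAML configuration file
#'
#' The file must contain the keys `attribute_names`, `concept_names`,
#' `attribute_items` and `concept_items` with the shapes documented in
#' [iat_stimuli()]. The format is chosen from the file extension
#' (`.json` vs. `.yaml`/`.yml`).
#'
#' @param path path to the configuration file.
#' @return An `iat_stimuli` object.
#' @export
read_stimuli <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("stimulus config '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop_validation(sprintf("unsupported stimulus config extension '.%s' (use .json or .yaml)", ext))
  )
  need <- c("attribute_names", "concept_names", "attribute_items", "concept_items")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop_validation(paste0("stimulus config is missing key(s): ", paste(missing, collapse = ", ")))
  # equal-length item lists may come back simplified to a 2-row matrix
  as_item_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) as.character(x[i, ]))
    else lapply(x, function(v) as.character(unlist(v, use.names = FALSE)))
  }
  iat_stimuli(
    attribute_names = as.character(unlist(raw$attribute_names)),
    concept_names   = as.character(unlist(raw$concept_names)),
    attribute_items = as_item_list(raw$attribute_items),
    concept_items   = as_item_list(raw$concept_items)
  )
}

#' Built-in example stimulus set (weight-bias IAT, synthetic)
#'
#' A small weight-attitude instrument in the style of the Project Implicit
#' weight IAT: positive/negative attribute words and image identifiers for
#' silhouettes of overweight vs. normal-weight individuals. The item lists
#' are synthetic stand-ins assembled for examples and simulation, not the
#' originals.
#'
#' @return An `iat_stimuli` object.
#' @export
example_stimuli <- function() {
  iat_stimuli(
    attribute_names = c("good", "bad"),
    concept_names   = c("overweight people", "thin people"),
    attribute_items = list(
      c("joy", "love", "peace", "wonderful", "pleasure", "glorious", "laughter", "happy"),
      c("agony", "terrible", "horrible", "nasty", "evil", "awful", "failure", "hurt")
    ),
    concept_items = list(
      paste0("overweight_silhouette_", 1:6, ".png"),
      paste0("thin_silhouette_", 1:6, ".png")
    )
  )
}
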