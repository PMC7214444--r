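#' Concept vocabulary with is-a hierarchy
#'
#' A `concept_vocabulary` holds a registry of codified medical concepts and a
#' directed acyclic graph of parent-to-child ("is-a") relations between them.
#' It is the unit against which concept sets and eligibility criteria are
#' operationalized: criteria reference a concept and may pull in its whole
#' descendant closure, mirroring how cohort definitions are built over a
#' standardized clinical vocabulary.
#'
#' @param concepts data.frame with columns `concept_id`, `domain`, `label`.
#'   `domain` must be one of `"condition"`, `"drug"`, `"measurement"`,
#'   `"procedure"`, `"demographic"`.
#' @param edges data.frame with columns `parent_id`, `child_id`; both must
#'   reference known concepts and the relation must be acyclic.
#' @return An object of class `concept_vocabulary`.
#' @examples
#' voc <- concept_vocabulary(
#'   data.frame(concept_id = c("A", "B", "C"),
#'              domain = "condition", label = c("root", "left", "right")),
#'   data.frame(parent_id = c("A", "A"), child_id = c("B", "C")))
#' descendants(voc, "A")
#' @export
concept_vocabulary <- function(concepts, edges) {
  stopifnot(is.data.frame(concepts), is.data.frame(edges))
  need <- c("concept_id", "domain", "label")
  if (!all(need %in% names(concepts)))
    stop("concepts must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(concepts$concept_id))
    stop("vocabulary error: duplicated concept_id in vocabulary")
  ok_dom <- c("condition", "drug", "measurement", "procedure", "demographic")
  bad <- setdiff(unique(concepts$domain), ok_dom)
  if (length(bad))
    stop("vocabulary error: unknown domain(s): ", paste(bad, collapse = ", "))
  if (nrow(edges)) {
    if (!all(c("parent_id", "child_id") %in% names(edges)))
      stop("edges must have columns parent_id, child_id")
    unknown <- setdiff(unique(c(edges$parent_id, edges$child_id)),
                       concepts$concept_id)
    if (length(unknown))
      stop("vocabulary error: hierarchy references unknown concept(s): ",
           paste(unknown, collapse = ", "))
  }
  children <- split(as.character(edges$child_id), as.character(edges$parent_id))
  voc <- structure(
    list(concepts = concepts, edges = edges, children = children),
    class = "concept_vocabulary")
  assert_acyclic(voc)
  voc
}

# Kahn's algorithm; stops if the is-a relation has a cycle.
assert_acyclic <- function(voc) {
  edges <- voc$edges
  if (!nrow(edges)) return(invisible(TRUE))
  indeg <- table(factor(edges$child_id, levels = voc$concepts$concept_id))
  indeg <- as.integer(indeg)
  names(indeg) <- voc$concepts$concept_id
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    node <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (kid in voc$children[[node]]) {
      indeg[kid] <- indeg[kid] - 1L
      if (indeg[kid] == 0L) queue <- c(queue, kid)
    }
  }
  if (seen < nrow(voc$concepts))
    stop("vocabulary error: hierarchy is not acyclic")
  invisible(TRUE)
}

#' @export
print.concept_vocabulary <- function(x, ...) {
  cat(sprintf("<concept_vocabulary> %d concepts, %d is-a relations\n",
              nrow(x$concepts), nrow(x$edges)))
  print(table(x$concepts$domain))
  invisible(x)
}

assert_known_concepts <- function(voc, ids) {
  unknown <- setdiff(ids, voc$concepts$concept_id)
  if (length(unknown))
    stop("vocabulary error: unknown concept(s): ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Transitive descendant closure of a concept
#'
#' Returns the concept itself together with every concept reachable through
#' the is-a relation (children, grandchildren, ...). Deterministic: the
#' result is sorted.
#'
#' @param vocabulary a [concept_vocabulary()].
#' @param concept_id a single concept identifier present in the vocabulary.
#' @return Character vector of concept ids (closure including the concept).
#' @export
descendants <- function(vocabulary, concept_id) {
  stopifnot(inherits(vocabulary, "concept_vocabulary"),
            length(concept_id) == 1L)
  assert_known_concepts(vocabulary, concept_id)
  out <- character(0)
  stack <- concept_id
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node %in% out) next
    out <- c(out, node)
    stack <- c(stack, vocabulary$children[[node]])
  }
  sort(out)
}

concept_domain <- function(vocabulary, ids) {
  m <- match(ids, vocabulary$concepts$concept_id)
  vocabulary$concepts$domain[m]
}

#' Declarative concept set
#'
#' A concept set names the concepts that define one clinical idea: a list of
#' included concepts (optionally with their whole descendant closure) minus a
#' list of excluded concepts (likewise optionally with descendants). This is
#' the declarative unit by which eligibility criteria are mapped onto the
#' vocabulary.
#'
#' @param include character vector of concept ids to include (may be empty).
#' @param exclude character vector of concept ids to remove from the
#'   included closure.
#' @param include_descendants,exclude_descendants logical, recycled along the
#'   respective id vectors: take the descendant closure of each id?
#' @return An object of class `concept_set`.
#' @seealso [resolve_concept_set()]
#' @export
concept_set <- function(include = character(0), exclude = character(0),
                        include_descendants = TRUE, exclude_descendants = TRUE) {
  include <- as.character(include); exclude <- as.character(exclude)
  inc <- data.frame(concept_id = include,
                    descendants = rep_len(as.logical(include_descendants),
                                          length(include)))
  exc <- data.frame(concept_id = exclude,
                    descendants = rep_len(as.logical(exclude_descendants),
                                          length(exclude)))
  structure(list(include = inc, exclude = exc), class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("<concept_set> include: %s; exclude: %s\n",
              paste0(x$include$concept_id,
                     ifelse(x$include$descendants, "+desc", ""),
                     collapse = ", "),
              if (nrow(x$exclude))
                paste0(x$exclude$concept_id,
                       ifelse(x$exclude$descendants, "+desc", ""),
                       collapse = ", ") else "(none)"))
  invisible(x)
}

#' Resolve a concept set against a vocabulary
#'
#' Expands the included entries (taking descendant closures where flagged),
#' then removes the expanded excluded entries. Membership is never negative:
#' the result is a plain set of concept ids.
#'
#' @param set a [concept_set()].
#' @param vocabulary a [concept_vocabulary()].
#' @return Sorted character vector of resolved concept ids.
#' @export
resolve_concept_set <- function(set, vocabulary) {
  stopifnot(inherits(set, "concept_set"),
            inherits(vocabulary, "concept_vocabulary"))
  expand <- function(tab) {
    if (!nrow(tab)) return(character(0))
    assert_known_concepts(vocabulary, tab$concept_id)
    unique(unlist(lapply(seq_len(nrow(tab)), function(i) {
      if (tab$descendants[i]) descendants(vocabulary, tab$concept_id[i])
      else tab$concept_id[i]
    })))
  }
  sort(setdiff(expand(set$include), expand(set$exclude)))
}

#' Packaged toy vocabulary
#'
#' Loads the small controlled vocabulary shipped with the package
#' (cardiometabolic conditions, drug classes with ingredients, laboratory
#' measurements, demographic levels) together with its is-a hierarchy. This
#' stands in for a full standardized vocabulary, which is licensed and out of
#' scope; concept ids are opaque package-local strings.
#'
#' @return A [concept_vocabulary()].
#' @export
toy_vocabulary <- function() {
  dir <- system.file("extdata", "vocab", package = "trialconcord",
                     mustWork = TRUE)
  read_vocabulary_dir(dir)
}

read_vocabulary_dir <- function(dir) {
  concepts <- utils::read.csv(file.path(dir, "vocabulary.csv"),
                              stringsAsFactors = FALSE)
  hier_path <- file.path(dir, "hierarchy.csv")
  edges <- if (file.exists(hier_path))
    utils::read.csv(hier_path, stringsAsFactors = FALSE)
  else data.frame(parent_id = character(0), child_id = character(0))
  concept_vocabulary(concepts, edges)
}
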