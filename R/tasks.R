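#' Define a PTM prediction task
#'
#' A task binds a name (e.g. `"Phosphorylation (S)"`) to the single amino
#' acid it targets (its *candidate residue*) and to the set of annotation
#' strings that mark a site as belonging to this task. Only candidate-residue
#' positions are ever labeled or scored for a task.
#'
#' @param task_name Unique task identifier.
#' @param candidate_residue One of the 20 standard amino-acid letters.
#' @param annotation_keys Non-empty character vector of annotation strings
#'   (UniProt feature descriptions) mapped to this task. Matching is exact
#'   after whitespace normalization.
#' @return An object of class `ptm_task`.
#' @seealso [default_task_registry()], [task_registry()]
#' @export
#' @examples
#' ptm_task("Phosphorylation (S)", "S", c("Phosphoserine", "Diphosphoserine"))
ptm_task <- function(task_name, candidate_residue, annotation_keys) {
  assert_that(is.character(task_name) && length(task_name) == 1L &&
                nzchar(task_name), "task_name must be a non-empty string")
  assert_that(is.character(candidate_residue) &&
                length(candidate_residue) == 1L &&
                candidate_residue %in% AA_STANDARD,
              paste0("candidate_residue must be one of the 20 standard ",
                     "amino-acid letters (got '", candidate_residue, "')"))
  annotation_keys <- normalize_annotation(unlist(annotation_keys))
  assert_that(length(annotation_keys) >= 1L && all(nzchar(annotation_keys)),
              "annotation_keys must be a non-empty character vector")
  structure(
    list(task_name = task_name,
         candidate_residue = candidate_residue,
         annotation_keys = unique(annotation_keys)),
    class = "ptm_task")
}

#' @export
print.ptm_task <- function(x, ...) {
  cat("<ptm_task> ", x$task_name, " [residue ", x$candidate_residue, ", ",
      length(x$annotation_keys), " annotation key(s)]\n", sep = "")
  invisible(x)
}

#' Build a task registry
#'
#' A registry is a named list of [ptm_task()] objects with unique task names;
#' it defines which PTM types a corpus, model, or report covers.
#'
#' @param tasks List of `ptm_task` objects.
#' @return An object of class `ptm_task_registry` (named list).
#' @export
task_registry <- function(tasks) {
  assert_that(length(tasks) >= 1L, "registry needs at least one task")
  assert_that(all(vapply(tasks, inherits, logical(1), "ptm_task")),
              "all registry entries must be ptm_task objects")
  nm <- vapply(tasks, `[[`, character(1), "task_name")
  assert_that(!anyDuplicated(nm), "task names must be unique in a registry")
  structure(stats::setNames(tasks, nm), class = "ptm_task_registry")
}

#' Load a task registry from a YAML file
#'
#' The file is a YAML list of records with fields `task_name`,
#' `candidate_residue`, and `annotation_keys`.
#'
#' @param path Path to a YAML task file.
#' @return A `ptm_task_registry`.
#' @export
read_task_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  task_registry(lapply(raw, function(r) {
    ptm_task(r$task_name, r$candidate_residue, r$annotation_keys)
  }))
}

#' The default 13-task PTM registry
#'
#' Thirteen PTM types — phosphorylation (S, T, Y), N- and O-linked
#' glycosylation, ubiquitination, acetylation, methylation (K, R),
#' SUMOylation, succinylation, and palmitoylation — with their UniProt
#' annotation strings, read from the editable file
#' `system.file("extdata", "ptm_tasks.yaml", package = "ptmtune")`.
#'
#' @return A `ptm_task_registry` with 13 tasks.
#' @export
default_task_registry <- function() {
  read_task_registry(system.file("extdata", "ptm_tasks.yaml",
                                 package = "ptmtune", mustWork = TRUE))
}

#' @export
print.ptm_task_registry <- function(x, ...) {
  cat("<ptm_task_registry> ", length(x), " task(s)\n", sep = "")
  for (t in x) {
    cat("  - ", t$task_name, " (", t$candidate_residue, ")\n", sep = "")
  }
  invisible(x)
}

# Collapse runs of whitespace and trim; annotation strings are matched
# exactly after this normalization.
normalize_annotation <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}
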