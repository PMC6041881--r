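# Cohort builder: reusable filter blocks composed into AND/OR containers per
# dataset, combined across datasets with UNION/INTERSECT/EXCEPT set algebra,
# and committed as versioned cohorts with stable per-project release
# identifiers. AND is per-row (SQL WHERE semantics); per-patient conjunction
# across rows is expressed as INTERSECT of containers.

PREDICATES <- c("equals", "in_set", "between", "matches_regex", "before", "after")

#' Build a reusable filter block
#'
#' @param column Column the predicate applies to.
#' @param predicate One of `equals`, `in_set`, `between`, `matches_regex`,
#'   `before`, `after` (the last two compare ISO dates).
#' @param ... Predicate parameters: `value` (equals), `values` (in_set),
#'   `lower`/`upper` (between), `pattern` (matches_regex), `date`
#'   (before/after).
#' @param description Human-readable intent, used by [describe_definition()].
#' @param filter_id Stable identifier; defaults to a digest of the content.
#' @return A `filter_block`.
#' @export
filter_block <- function(column, predicate, ..., description = "", filter_id = NULL) {
  predicate <- match.arg(predicate, PREDICATES)
  params <- list(...)
  need <- switch(predicate, equals = "value", in_set = "values",
                 between = c("lower", "upper"), matches_regex = "pattern",
                 before = "date", after = "date")
  miss <- setdiff(need, names(params))
  if (length(miss)) abort(sprintf("predicate '%s' needs parameter(s): %s",
                                  predicate, paste(miss, collapse = ", ")))
  if (predicate == "matches_regex") {
    ok <- tryCatch({ grepl(params$pattern, ""); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("regex does not compile: %s", params$pattern))
  }
  if (is.null(filter_id)) {
    filter_id <- paste0("F", substr(digest::digest(list(column, predicate, params)), 1, 8))
  }
  structure(list(node = "filter", filter_id = filter_id, column = column,
                 predicate = predicate, params = params, description = description),
            class = "filter_block")
}

#' Combine filters into an AND/OR container
#'
#' @param mode `"AND"` (row satisfies all children) or `"OR"`.
#' @param ... Child `filter_block`s or nested `filter_container`s (non-empty).
#' @return A `filter_container`.
#' @export
filter_container <- function(mode, ...) {
  mode <- match.arg(mode, c("AND", "OR"))
  children <- list(...)
  if (length(children) == 0) abort("container must have at least one child")
  structure(list(node = "container", mode = mode, children = children),
            class = "filter_container")
}

#' Cohort definition tree nodes
#'
#' `cohort_leaf()` attaches a filter container to a dataset; `cohort_op()`
#' combines identifier sets with set algebra (`EXCEPT` is strictly binary and
#' ordered: `EXCEPT(a, b) = a` minus `b`); `cohort_definition()` wraps the root.
#'
#' @param dataset Dataset id or name.
#' @param container A [filter_container()] (or single [filter_block()]).
#' @return Tree node lists of class `cohort_node` / `cohort_definition`.
#' @export
cohort_leaf <- function(dataset, container) {
  if (inherits(container, "filter_block")) container <- filter_container("AND", container)
  structure(list(node = "leaf", dataset = dataset, container = container),
            class = "cohort_node")
}

#' @rdname cohort_leaf
#' @param op `"UNION"`, `"INTERSECT"` (n-ary) or `"EXCEPT"` (binary).
#' @param ... Child `cohort_node`s.
#' @export
cohort_op <- function(op, ...) {
  op <- match.arg(op, c("UNION", "INTERSECT", "EXCEPT"))
  children <- list(...)
  if (op == "EXCEPT" && length(children) != 2) abort("EXCEPT takes exactly two children")
  if (length(children) == 0) abort("set operation needs at least one child")
  structure(list(node = "op", op = op, children = children), class = "cohort_node")
}

#' @rdname cohort_leaf
#' @param root Root `cohort_node`.
#' @param description Free-text description of the cohort logic.
#' @param definition_id Stable identifier; defaults to a digest of the tree.
#' @export
cohort_definition <- function(root, description = "", definition_id = NULL) {
  if (inherits(root, "filter_container") || inherits(root, "filter_block")) {
    abort("the definition root must be a cohort_leaf or cohort_op, not a bare filter")
  }
  if (is.null(definition_id)) {
    definition_id <- paste0("CD", substr(digest::digest(unclass_tree(root)), 1, 8))
  }
  structure(list(definition_id = definition_id, root = root, description = description),
            class = "cohort_definition")
}

unclass_tree <- function(x) {
  if (is.list(x)) { x <- unclass(x); x[] <- lapply(x, unclass_tree) }
  x
}

# ---- (de)serialisation -----------------------------------------------------

#' Read / write a cohort definition as JSON
#'
#' @param definition A `cohort_definition`.
#' @param path JSON file path.
#' @return `read_cohort_definition()` returns a `cohort_definition`.
#' @export
write_cohort_definition <- function(definition, path) {
  write_json_file(unclass_tree(unclass(definition)), path)
}

#' @rdname write_cohort_definition
#' @export
read_cohort_definition <- function(path) {
  doc <- read_json_file(path)
  reclass <- function(nd) {
    if (!is.list(nd) || is.null(nd$node)) return(nd)
    if (nd$node == "filter") {
      nd$params <- lapply(nd$params, function(p) if (is.list(p)) unlist(p) else p)
      return(structure(nd, class = "filter_block"))
    }
    nd$children <- lapply(nd$children, reclass)
    if (nd$node == "container") return(structure(nd, class = "filter_container"))
    if (nd$node == "leaf") { nd$container <- reclass(nd$container); return(structure(nd, class = "cohort_node")) }
    structure(nd, class = "cohort_node")
  }
  structure(list(definition_id = doc$definition_id,
                 root = reclass(doc$root),
                 description = doc$description %||% ""),
            class = "cohort_definition")
}

# ---- evaluation ------------------------------------------------------------

predicate_mask <- function(block, table) {
  if (!block$column %in% names(table)) {
    abort(sprintf("filter %s references unknown column '%s'", block$filter_id, block$column))
  }
  v <- table[[block$column]]
  p <- block$params
  m <- switch(block$predicate,
    equals = !is.na(v) & v == as.character(p$value),
    in_set = !is.na(v) & v %in% as.character(unlist(p$values)),
    between = {
      num <- suppressWarnings(as.numeric(v))
      !is.na(num) & num >= as.numeric(p$lower) & num <= as.numeric(p$upper)
    },
    matches_regex = !is.na(v) & grepl(p$pattern, v),
    before = {
      d <- as.Date(v, format = "%Y-%m-%d")
      !is.na(d) & d < as.Date(p$date)
    },
    after = {
      d <- as.Date(v, format = "%Y-%m-%d")
      !is.na(d) & d > as.Date(p$date)
    })
  m
}

container_mask <- function(container, table) {
  masks <- lapply(container$children, function(ch) {
    if (inherits(ch, "filter_block") || identical(ch$node, "filter")) {
      predicate_mask(ch, table)
    } else {
      container_mask(ch, table)
    }
  })
  if (nrow(table) == 0) return(logical(0))
  Reduce(if (container$mode == "AND") `&` else `|`, masks)
}

#' Evaluate a filter container against one dataset
#'
#' Applies the container's per-row logic to the dataset's table (live, or
#' reconstructed as at `as_at`) and collects the private identifiers of the
#' satisfying rows. Identifiers come from the dataset's catalogue item flagged
#' `Internal` with role `"identifier"`.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @param container A [filter_container()] or [filter_block()].
#' @param as_at Optional UTC timestamp for bitemporal evaluation.
#' @return Sorted character vector of private identifiers.
#' @export
evaluate_container <- function(store, dataset, container, as_at = NULL) {
  if (inherits(container, "filter_block")) container <- filter_container("AND", container)
  entry <- get_entry(store, dataset)
  idcol <- entry_identifier_column(entry)
  table <- if (is.null(as_at)) live_table(store, dataset)
           else reconstruct_as_at(store, dataset, as_at)
  if (nrow(table) == 0) return(character())
  mask <- container_mask(container, table)
  sort(unique(table[[idcol]][mask & !is.na(table[[idcol]])]))
}

#' Evaluate a cohort definition
#'
#' Set-algebra evaluation of the definition tree: leaves evaluate their filter
#' container against a dataset; internal nodes combine identifier sets with
#' UNION, INTERSECT or EXCEPT.
#'
#' @param store A `dm_store`.
#' @param definition A `cohort_definition`.
#' @param as_at Optional UTC timestamp for bitemporal evaluation.
#' @return Sorted character vector of private identifiers.
#' @export
evaluate_definition <- function(store, definition, as_at = NULL) {
  eval_node <- function(nd) {
    if (identical(nd$node, "leaf")) {
      return(evaluate_container(store, nd$dataset, nd$container, as_at = as_at))
    }
    sets <- lapply(nd$children, eval_node)
    out <- switch(nd$op,
      UNION = Reduce(union, sets),
      INTERSECT = Reduce(intersect, sets),
      EXCEPT = setdiff(sets[[1]], sets[[2]]))
    sort(unique(out))
  }
  eval_node(definition$root)
}

#' Render a cohort definition as a deterministic logic document
#'
#' @param definition A `cohort_definition`.
#' @return Single string; byte-identical across runs for the same definition.
#' @export
describe_definition <- function(definition) {
  fmt_params <- function(p) {
    paste(vapply(names(p), function(nm) {
      sprintf("%s=%s", nm, paste(as.character(unlist(p[[nm]])), collapse = ","))
    }, character(1)), collapse = " ")
  }
  render <- function(nd, depth) {
    pad <- strrep("  ", depth)
    if (inherits(nd, "filter_block") || identical(nd$node, "filter")) {
      desc <- if (nzchar(nd$description %||% "")) paste0("  # ", nd$description) else ""
      return(sprintf("%s[%s] %s %s %s%s", pad, nd$filter_id, nd$column,
                     nd$predicate, fmt_params(nd$params), desc))
    }
    if (identical(nd$node, "container")) {
      kids <- vapply(nd$children, render, character(1), depth = depth + 1)
      return(paste(c(sprintf("%s%s {", pad, nd$mode), kids, sprintf("%s}", pad)),
                   collapse = "\n"))
    }
    if (identical(nd$node, "leaf")) {
      return(paste(c(sprintf("%sDATASET %s", pad, nd$dataset),
                     render(nd$container, depth + 1)), collapse = "\n"))
    }
    kids <- vapply(nd$children, render, character(1), depth = depth + 1)
    paste(c(sprintf("%s%s {", pad, nd$op), kids, sprintf("%s}", pad)), collapse = "\n")
  }
  header <- sprintf("COHORT %s%s", definition$definition_id,
                    if (nzchar(definition$description %||% ""))
                      paste0(": ", definition$description) else "")
  paste(c(header, render(definition$root, 0)), collapse = "\n")
}

# ---- projects and release identifiers --------------------------------------

project_path <- function(store, project_id) {
  file.path(store$path, "projects", paste0(project_id, ".json"))
}

#' Register a research project
#'
#' Each project owns a seeded pseudonym generator and a persistent private
#' identifier to release identifier map, so refreshes reuse the same release
#' identifiers and different projects can never link records through them.
#'
#' @param store A `dm_store`.
#' @param project_id Unique project identifier.
#' @param seed Integer seed for the project's release-identifier generator.
#'   Defaults to a hash of the project id.
#' @return The project record (invisibly).
#' @export
create_project <- function(store, project_id, seed = NULL) {
  p <- project_path(store, project_id)
  if (file.exists(p)) abort(sprintf("project already exists: %s", project_id))
  if (is.null(seed)) {
    seed <- sum(utf8ToInt(project_id) * seq_along(utf8ToInt(project_id))) %% 2147480000L
  }
  rec <- list(project_id = project_id, seed = as.integer(seed),
              release_map = stats::setNames(list(), character()), minted = 0L)
  write_json_file(rec, p)
  invisible(rec)
}

read_project <- function(store, project_id) {
  p <- project_path(store, project_id)
  rec <- read_json_file(p)
  if (is.null(rec)) abort(sprintf("unknown project: %s", project_id))
  rec$release_map <- lapply(rec$release_map, as.character)
  rec
}

# 12-hex release tokens from the project's seeded stream. Tokens containing a
# run of 10+ consecutive digits are re-minted, so a release-identifier column
# can never hold a window for the CHI scanner to flag.
mint_release_ids <- function(project, n_needed) {
  existing <- unlist(project$release_map, use.names = FALSE)
  out <- character(0)
  k <- project$minted
  while (length(out) < n_needed) {
    tok <- withr::with_seed((project$seed + k * 7919L) %% 2147483629L, {
      paste(sample(c(as.character(0:9), letters[1:6]), 12, replace = TRUE), collapse = "")
    })
    k <- k + 1L
    if (!grepl("[0-9]{10}", tok) && !tok %in% c(existing, out)) out <- c(out, tok)
  }
  list(tokens = out, minted = k)
}

#' Retrieve (or extend) a project's release-identifier map
#'
#' Previously seen private identifiers keep their release identifier; new ones
#' are minted from the project's seeded generator. The map is injective and
#' grows monotonically.
#'
#' @param store A `dm_store`.
#' @param project_id Registered project.
#' @param private_ids Private identifiers that need release identifiers.
#' @return Named character vector `private_id -> release_id`.
#' @export
project_release_map <- function(store, project_id, private_ids = character()) {
  proj <- read_project(store, project_id)
  new_ids <- setdiff(private_ids, names(proj$release_map))
  if (length(new_ids)) {
    minted <- mint_release_ids(proj, length(new_ids))
    for (i in seq_along(new_ids)) proj$release_map[[new_ids[i]]] <- minted$tokens[i]
    proj$minted <- minted$minted
    write_json_file(proj, project_path(store, project_id))
  }
  unlist(proj$release_map[private_ids %||% character()]) %||%
    stats::setNames(character(), character())
}

# ---- committed cohorts -----------------------------------------------------

cohorts_path <- function(store) file.path(store$path, "cohorts.json")

read_cohorts <- function(store) read_json_file(cohorts_path(store), default = list())

#' Commit a cohort: freeze members and assign release identifiers
#'
#' Evaluates the definition, freezes the member set, assigns release
#' identifiers from the project's persistent map (stable across versions), and
#' stores the committed cohort with a strictly increasing version number per
#' definition and project. An empty member set is committed with a warning.
#'
#' @param store A `dm_store`.
#' @param definition A `cohort_definition`.
#' @param project_id Registered project.
#' @param as_at Optional UTC timestamp: evaluate against the data as at that time.
#' @return The committed cohort record: `cohort_id`, `version`, `members`,
#'   `release_map`, embedded `definition`.
#' @export
commit_cohort <- function(store, definition, project_id, as_at = NULL) {
  proj <- read_project(store, project_id)  # errors on unknown project
  members <- evaluate_definition(store, definition, as_at = as_at)
  if (length(members) == 0) {
    warning("committing an empty cohort", call. = FALSE)
  }
  rel_map <- project_release_map(store, project_id, members)
  cohorts <- read_cohorts(store)
  versions <- vapply(cohorts, function(co) {
    if (identical(co$definition_id, definition$definition_id) &&
        identical(co$project_id, project_id)) as.integer(co$version) else 0L
  }, integer(1))
  ids <- vapply(cohorts, function(co) co$cohort_id, character(1))
  rec <- list(
    cohort_id = fresh_id("C", ids),
    definition_id = definition$definition_id,
    project_id = project_id,
    version = (if (length(versions)) max(versions) else 0L) + 1L,
    committed_at = ts_now(),
    members = as.list(members),
    release_map = as.list(rel_map),
    definition = unclass_tree(unclass(definition))
  )
  cohorts <- c(cohorts, list(rec))
  write_json_file(cohorts, cohorts_path(store))
  rec$members <- members
  rec$release_map <- rel_map
  rec
}

#' Fetch a committed cohort by id
#'
#' @param store A `dm_store`.
#' @param cohort_id Committed cohort identifier.
#' @return The committed cohort record.
#' @export
get_cohort <- function(store, cohort_id) {
  cohorts <- read_cohorts(store)
  for (co in cohorts) if (identical(co$cohort_id, cohort_id)) {
    co$members <- as.character(unlist(co$members))
    co$release_map <- stats::setNames(as.character(unlist(co$release_map)),
                                      names(co$release_map))
    return(co)
  }
  abort(sprintf("unknown cohort: %s", cohort_id))
}
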