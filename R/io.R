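# Reading delimited meta-analytic data sets with a column schema, and
# JSON serialization of fitted trees.

#' Read a meta-analytic data set from a delimited text file
#'
#' The schema declares column roles: which column holds the effect size,
#' which the sampling variance (or standard error, squared on input), and
#' the type of each moderator column.  The schema may be given as an R
#' list or as a path to a JSON (or YAML, if the yaml package is
#' installed) sidecar file with the same structure:
#'
#' ```
#' list(effect = "d", variance = "vi",        # or se = "se_d"
#'      moderators = list(x1 = "binary", x2 = "ordinal", ...),
#'      ordinal_levels = list(x2 = c("low", "mid", "high")),
#'      id = "study")                          # optional
#' ```
#'
#' @param path delimited text file with a header row; the separator is
#'   sniffed from the first line (comma or tab).
#' @param schema schema list or path to a sidecar file.
#' @return An [effect_size_set()].
#' @export
read_dataset <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- read_schema(schema)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c(schema$effect,
            schema$variance %||% schema$se,
            names(schema$moderators))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("file lacks columns: ", paste(miss, collapse = ", "))
  d <- df[[schema$effect]]
  vi <- if (!is.null(schema$variance)) df[[schema$variance]]
        else df[[schema$se]]^2
  bad <- which(is.na(d) | is.na(vi))
  if (length(bad) > 0L)
    stop("missing effect size or variance in rows: ",
         paste(bad, collapse = ", "))
  mods <- names(schema$moderators)
  types <- unlist(schema$moderators, use.names = FALSE)
  X <- df[mods]
  for (m in mods) {
    type <- schema$moderators[[m]]
    if (type == "ordinal" && !is.null(schema$ordinal_levels[[m]]))
      X[[m]] <- ordered(X[[m]], levels = schema$ordinal_levels[[m]])
    else if (type == "nominal") X[[m]] <- factor(X[[m]])
  }
  ids <- if (!is.null(schema$id)) df[[schema$id]] else NULL
  effect_size_set(d, vi, X, types = types, ids = ids)
}

read_schema <- function(path) {
  if (grepl("\\.(ya?ml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML schema requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Serialize a fitted tree to a JSON document
#'
#' Writes the pruned tree (nodes, split rules, per-node sizes and
#' summaries), the subgroup fit (tau2, Q_B, df, p-value, per-subgroup
#' estimates and confidence bounds), the pruning parameter, seed and
#' package version.  [read_tree()] parses the document back; writing the
#' parsed document again is lossless.
#'
#' @param fit a `"metatree"`.
#' @param path output file path.
#' @return The document (invisibly).
#' @export
write_tree <- function(fit, path) {
  stopifnot(inherits(fit, "metatree"))
  tree <- fit$tree
  S <- nrow(tree$splits)
  rules <- lapply(seq_len(S), function(s) {
    sp <- tree$splits[s, ]
    r <- list(node = sp$node, moderator = tree$enc$varnames[sp$var],
              kind = if (sp$kind == 0L) "threshold" else "subset")
    if (sp$kind == 0L) r$threshold <- sp$threshold
    else {
      labs <- tree$enc$levels[[sp$var]]
      r$left_levels <- as.list(labs[tree$left_levels[[s]]])
      r$right_levels <- as.list(labs[tree$right_levels[[s]]])
    }
    r
  })
  tids <- sort(unique(tree$term))
  doc <- list(
    package = "metatree",
    version = as.character(utils::packageVersion("metatree")),
    model = fit$model, c = fit$c, size = fit$size,
    seed = fit$cv$seed,
    splits = rules,
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i)
      as.list(tree$nodes[i, c("id", "parent", "n", "mean", "Q")])),
    terminal_nodes = as.list(tids),
    fit = list(tau2 = fit$fit$tau2, Q_B = fit$fit$Q_B, Q_T = fit$fit$Q_T,
               df = fit$fit$df, pvalue = fit$fit$pvalue,
               estimates = as.list(fit$fit$est),
               k = as.list(fit$fit$k),
               ci_lower = as.list(fit$fit$ci[, 1]),
               ci_upper = as.list(fit$fit$ci[, 2])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(doc)
}

#' Read a serialized tree document
#'
#' @param path a JSON file written by [write_tree()].
#' @return The parsed document (a list).
#' @export
read_tree <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
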