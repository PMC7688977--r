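# Simulated server/node/task orchestration with an aggregate-only payload
# contract. Nodes are in-process actors holding their site's cohort table;
# only Task and TaskResult objects cross the site boundary, and every
# returned payload is audited against the "aggregates only" rule. A socket
# transport could be swapped in behind the same interface.

#' Create a site node
#'
#' A node holds one site's patient-level cohort table and a registry of
#' named operations it is willing to execute. Patient-level data is
#' reachable only from operations run inside the node; callers receive the
#' operations' aggregate return values.
#'
#' @param site_id Opaque site identifier (e.g. `"NL"`).
#' @param data The site's cohort data frame.
#' @return An object of class `fed_node`.
#' @export
fed_node <- function(site_id, data) {
  stopifnot(is.character(site_id), length(site_id) == 1, is.data.frame(data))
  node <- new.env(parent = emptyenv())
  node$site_id <- site_id
  node$data <- data
  node$ops <- list()
  node$cache <- new.env(parent = emptyenv())
  node$online <- TRUE
  class(node) <- "fed_node"
  for (op in names(default_node_ops))
    node_register(node, op, default_node_ops[[op]])
  node
}

#' Register an executable operation at a node
#'
#' @param node A `fed_node`.
#' @param name Operation name tasks refer to.
#' @param fun Function `(data, payload, cache)` returning an aggregate.
#' @export
node_register <- function(node, name, fun) {
  stopifnot(inherits(node, "fed_node"), is.function(fun))
  node$ops[[name]] <- fun
  invisible(node)
}

node_design <- function(data, cache, spec) {
  key <- paste(spec$label, paste(spec_columns(spec), collapse = "|"), sep = "#")
  if (is.null(cache[[key]]))
    cache[[key]] <- build_design_matrix(data, spec)
  cache[[key]]
}

# Operations every node ships with. Each returns aggregates whose dimensions
# depend only on the model size p, the event-grid size K, or the (closed)
# level list of a categorical -- never on the site's number of records.
default_node_ops <- list(
  n_rows = function(data, payload, cache) nrow(data),
  column_sums = function(data, payload, cache) {
    x <- data[[payload$variable]]
    if (!is.numeric(x)) stopf("'%s' is not numeric", payload$variable)
    c(sum = sum(x, na.rm = TRUE), n = sum(!is.na(x)))
  },
  level_counts = function(data, payload, cache) {
    x <- data[[payload$variable]]
    if (is.null(x)) stopf("no column '%s'", payload$variable)
    if (!is.factor(x)) x <- factor(x)
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  },
  event_times = function(data, payload, cache)
    sort(unique(deci(data$time)[data$event == 1])),
  design_column_sums = function(data, payload, cache) {
    X <- node_design(data, cache, payload$spec)
    list(colsum = colSums(X), n = nrow(X))
  },
  cox_aggregates = function(data, payload, cache) {
    X <- node_design(data, cache, payload$spec)
    if (!is.null(payload$center))
      X <- sweep(X, 2, payload$center)
    cox_local_aggregates(data$time, data$event, X,
                         grid = payload$grid, beta = payload$beta)
  }
)

#' Create a coordinating server
#'
#' The server registers sites, queues tasks, collects results, and audits
#' every cross-boundary payload. All payloads are appended to an in-memory
#' audit trail and, optionally, a JSON-lines audit file.
#'
#' @param audit_file Optional path of a JSON-lines audit log (one record per
#'   returned payload).
#' @return An object of class `fed_server`.
#' @export
fed_server <- function(audit_file = NULL) {
  srv <- new.env(parent = emptyenv())
  srv$sites <- list()
  srv$queue <- list()     # task_id -> list(task, pending site ids)
  srv$results <- list()   # task_id -> list of fed_task_result
  srv$audit <- list()
  srv$audit_file <- audit_file
  srv$task_counter <- 0L
  if (!is.null(audit_file) && file.exists(audit_file)) unlink(audit_file)
  class(srv) <- "fed_server"
  srv
}

#' Register a node at the server
#'
#' @param server A `fed_server`.
#' @param node A `fed_node`.
#' @export
register_site <- function(server, node) {
  stopifnot(inherits(server, "fed_server"), inherits(node, "fed_node"))
  server$sites[[node$site_id]] <- node
  invisible(server)
}

#' Construct a computation task
#'
#' @param operation Registered operation name.
#' @param payload Named list of parameters (e.g. the current coefficient
#'   vector); must not contain record-level arrays.
#' @param sites Target site ids.
#' @param task_id Optional explicit id; generated when omitted at submission.
#' @return An object of class `fed_task`.
#' @export
fed_task <- function(operation, payload = list(), sites, task_id = NULL) {
  structure(list(task_id = task_id, operation = operation,
                 payload = payload, sites = sites),
            class = "fed_task")
}

#' Submit a task to the server queue
#'
#' The task is queued once per target site; re-submitting an already known
#' `task_id` is rejected (idempotence).
#'
#' @param server A `fed_server`.
#' @param task A `fed_task`.
#' @return The task id, invisibly usable with [collect_results()].
#' @export
submit_task <- function(server, task) {
  stopifnot(inherits(server, "fed_server"), inherits(task, "fed_task"))
  if (length(task$sites) == 0) stopf("task targets no sites")
  unknown <- setdiff(task$sites, names(server$sites))
  if (length(unknown)) stopf("unknown site '%s'", unknown[1])
  if (is.null(task$task_id)) {
    server$task_counter <- server$task_counter + 1L
    task$task_id <- sprintf("task-%05d", server$task_counter)
  }
  if (!is.null(server$queue[[task$task_id]]) ||
      !is.null(server$results[[task$task_id]]))
    stopf("duplicate task_id '%s'", task$task_id)
  server$queue[[task$task_id]] <- list(task = task, pending = task$sites)
  task$task_id
}

payload_shapes <- function(x) {
  shapes <- list()
  walk <- function(v, path) {
    if (is.list(v) && !is.data.frame(v)) {
      nm <- names(v) %||% as.character(seq_along(v))
      for (i in seq_along(v)) walk(v[[i]], c(path, nm[i]))
    } else if (is.numeric(v) || is.integer(v) || is.logical(v)) {
      shapes[[paste(path, collapse = "$")]] <<- dim(v) %||% length(v)
    }
  }
  walk(x, character())
  shapes
}

#' Audit a task result against the aggregate-only contract
#'
#' Fails iff any numeric array in the result's aggregate payload has a
#' dimension equal to the site's record count `site_n`, unless `site_n`
#' coincides with a dimension legitimately derived from the model size `p`
#' or the event-grid size `K`. This is the enforcement hook for the rule
#' that nodes only return aggregated data.
#'
#' @param result A `fed_task_result`.
#' @param site_n The site's number of records.
#' @param p Number of model covariate columns (0 when not applicable).
#' @param K Number of distinct event times (0 when not applicable).
#' @return `TRUE` (pass) or `FALSE` (record-level leak suspected).
#' @export
audit_payload <- function(result, site_n, p = 0L, K = 0L) {
  shapes <- payload_shapes(result$aggregate)
  allowed <- unique(c(0L, 1L, 2L, as.integer(p), as.integer(K)))
  if (site_n %in% allowed) return(TRUE)
  for (d in shapes) if (any(d == site_n)) return(FALSE)
  TRUE
}

node_execute <- function(node, task) {
  op <- node$ops[[task$operation]]
  res <- if (is.null(op)) {
    list(aggregate = NULL, status = "error",
         message = sprintf("operation '%s' not registered at site %s",
                           task$operation, node$site_id))
  } else {
    tryCatch(
      list(aggregate = op(node$data, task$payload, node$cache),
           status = "ok", message = ""),
      error = function(e) list(aggregate = NULL, status = "error",
                               message = conditionMessage(e)))
  }
  structure(list(task_id = task$task_id, site_id = node$site_id,
                 aggregate = res$aggregate, status = res$status,
                 message = res$message),
            class = "fed_task_result")
}

audit_record <- function(server, task, result) {
  node <- server$sites[[result$site_id]]
  p <- length(task$payload$beta %||% numeric())
  if (p == 0 && !is.null(task$payload$spec))
    p <- length(spec_columns(task$payload$spec))
  K <- length(task$payload$grid %||% numeric())
  pass <- audit_payload(result, nrow(node$data), p, K)
  rec <- list(task_id = task$task_id, site_id = result$site_id,
              operation = task$operation,
              shapes = payload_shapes(result$aggregate),
              bytes = as.integer(utils::object.size(result$aggregate)),
              p = p, K = K, pass = pass)
  server$audit[[length(server$audit) + 1L]] <- rec
  if (!is.null(server$audit_file))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = server$audit_file, append = TRUE, sep = "")
  pass
}

#' Collect the results of a submitted task
#'
#' Simulated pickup: every pending target node executes the task; results
#' are audited, stored and returned ordered by site id. A node that is
#' offline leaves a missing result, reported as a timeout-style error
#' listing the missing sites.
#'
#' @param server A `fed_server`.
#' @param task_id Id returned by [submit_task()].
#' @param expected Number of results required (default: all target sites).
#' @return List of `fed_task_result`, ordered by `site_id`.
#' @export
collect_results <- function(server, task_id, expected = NULL) {
  entry <- server$queue[[task_id]]
  if (is.null(entry) && is.null(server$results[[task_id]]))
    stopf("unknown task '%s'", task_id)
  if (!is.null(entry)) {
    for (sid in entry$pending) {
      node <- server$sites[[sid]]
      if (!isTRUE(node$online)) next
      res <- node_execute(node, entry$task)
      audit_record(server, entry$task, res)
      server$results[[task_id]] <- c(server$results[[task_id]], list(res))
    }
    server$queue[[task_id]] <- NULL
    got <- vapply(server$results[[task_id]] %||% list(),
                  function(r) r$site_id, "")
    missing <- setdiff(entry$task$sites, got)
    expected <- expected %||% length(entry$task$sites)
    if (length(server$results[[task_id]] %||% list()) < expected)
      stopf("timeout: no result from site(s) %s",
            paste(missing, collapse = ", "))
  }
  out <- server$results[[task_id]]
  out[order(vapply(out, function(r) r$site_id, ""))]
}

#' Assemble an in-process federation from per-site cohort tables
#'
#' Convenience constructor: one node per named cohort, all registered at a
#' fresh server.
#'
#' @param cohorts Named list of cohort data frames; names are site ids.
#' @param audit_file Optional JSON-lines audit log path.
#' @return An object of class `federation` (list with `server`, `nodes`).
#' @export
federation <- function(cohorts, audit_file = NULL) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            !is.null(names(cohorts)), all(names(cohorts) != ""))
  server <- fed_server(audit_file)
  nodes <- lapply(names(cohorts), function(sid) {
    node <- fed_node(sid, cohorts[[sid]])
    register_site(server, node)
    node
  })
  names(nodes) <- names(cohorts)
  structure(list(server = server, nodes = nodes), class = "federation")
}

# Submit an operation to all (or some) sites and return ok results, erroring
# cleanly when any site reports an error.
fed_submit <- function(fed, operation, payload = list(), sites = NULL) {
  stopifnot(inherits(fed, "federation"))
  sites <- sites %||% names(fed$nodes)
  id <- submit_task(fed$server, fed_task(operation, payload, sites))
  out <- collect_results(fed$server, id)
  bad <- Filter(function(r) r$status != "ok", out)
  if (length(bad))
    stopf("site %s failed task '%s': %s", bad[[1]]$site_id, operation,
          bad[[1]]$message)
  out
}

#' Summarise the server's payload audit trail
#'
#' @param fed A `federation` (or `fed_server`).
#' @return Data frame with one row per audited payload (`task_id, site_id,
#'   operation, bytes, p, K, pass`).
#' @export
audit_report <- function(fed) {
  srv <- if (inherits(fed, "federation")) fed$server else fed
  stopifnot(inherits(srv, "fed_server"))
  recs <- srv$audit
  data.frame(
    task_id = vapply(recs, `[[`, "", "task_id"),
    site_id = vapply(recs, `[[`, "", "site_id"),
    operation = vapply(recs, `[[`, "", "operation"),
    bytes = vapply(recs, `[[`, 0L, "bytes"),
    p = vapply(recs, `[[`, 0L, "p"),
    K = vapply(recs, `[[`, 0L, "K"),
    pass = vapply(recs, `[[`, TRUE, "pass"),
    stringsAsFactors = FALSE
  )
}
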