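# Bridge to the bundled RDKit worker script.
#
# All chemistry (SMILES handling, macrocycle division, conformer embedding,
# descriptor and fingerprint calculation) is delegated to RDKit through
# inst/python/chem_backend.py.  Requests and responses are JSON files; one
# process is spawned per call, so callers batch aggressively.

the_backend <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for chemistry
#'
#' Resolution order: `options(pepperm.python=)`, the `PEPPERM_PYTHON`
#' environment variable, then `python` and `python3` on the `PATH`.  The
#' interpreter must be able to `import rdkit`.
#'
#' @return Path to the Python executable.
#' @export
pepperm_python <- function() {
  if (!is.null(the_backend$python)) return(the_backend$python)
  candidates <- c(
    getOption("pepperm.python", ""),
    Sys.getenv("PEPPERM_PYTHON", ""),
    Sys.which("python"),
    Sys.which("python3")
  )
  candidates <- candidates[nzchar(candidates)]
  for (py in candidates) {
    ok <- tryCatch(
      system2(py, c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE) == 0,
      error = function(e) FALSE, warning = function(w) FALSE
    )
    if (isTRUE(ok)) {
      the_backend$python <- py
      return(py)
    }
  }
  backend_error("no Python interpreter with rdkit found (set PEPPERM_PYTHON)")
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "pepperm")
  if (!nzchar(path)) backend_error("chem_backend.py not found in installation")
  path
}

#' @keywords internal
run_backend <- function(task, payload = list()) {
  payload$task <- task
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(pepperm_python(), c(backend_script(), req, res),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(res)) {
    backend_error(sprintf("chemistry backend failed (task '%s', status %d)",
                          task, status))
  }
  out <- jsonlite::fromJSON(res, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!isTRUE(out$ok)) {
    backend_error(sprintf("chemistry backend error (task '%s'): %s",
                          task, out$error %||% "unknown"))
  }
  out
}

# run a per-molecule jobs task and raise the given condition class on the
# first failed job
backend_jobs <- function(task, jobs, error_class = "pepperm_chem_error", ...) {
  out <- run_backend(task, c(list(jobs = jobs), list(...)))
  for (r in out$results) {
    if (!isTRUE(r$ok)) {
      pepperm_error(error_class, sprintf("%s: %s", task, r$error %||% "failed"))
    }
  }
  out$results
}
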