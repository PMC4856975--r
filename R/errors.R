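# Classed condition helper: every domain error carries a machine-readable
# subclass so the CLI can map it to an exit code and tests can assert on it.
bk_stop <- function(type, msg, ...) {
  stop(structure(class = c(type, "bundlekit_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

bk_log <- function(level, module, msg, ...) {
  if (bk_log_enabled(level))
    message(sprintf("[%s] %s: %s", level, module, sprintf(msg, ...)))
  invisible(NULL)
}

.bk_log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

bk_log_enabled <- function(level) {
  thr <- getOption("bundlekit.log_level", "info")
  .bk_log_levels[[level]] >= .bk_log_levels[[thr]]
}
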