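#' Hierarchical statechart machines
#'
#' A minimal hierarchical state-machine substrate: states with substates,
#' one initial child per composite state, orthogonal (parallel) regions,
#' per-state tick timers, and guarded, event-triggered transitions.  The
#' three cell behaviors of the simulator are declared as machines on this
#' engine; the engine itself contains no cell-specific code.
#'
#' Transition priority is fixed and documented: among enabled transitions
#' the one with the deepest source state fires; remaining ties are broken by
#' declaration order (or raise an error in strict mode).  Exit actions run
#' inner to outer, entry actions outer to inner.  Entering a state restarts
#' its timer.
#'
#' @param name state name, unique within the machine.
#' @param parent name of the parent state, or `NULL` for the root.
#' @param initial is this the default entry child of its parent?
#' @param parallel does this state hold orthogonal regions (all children
#'   active simultaneously)?
#' @param timer optional timer duration in ticks; when the state has been
#'   active for `timer` ticks its `"timeout"` transition fires.
#' @param on_entry,on_exit optional functions of the machine context.
#' @return `sc_state()` returns a state description used by [sc_machine()].
#' @seealso [sc_machine()], [sc_instantiate()], [sc_dispatch()], [sc_tick()]
#' @export
sc_state <- function(name, parent = NULL, initial = FALSE, parallel = FALSE,
                     timer = NULL, on_entry = NULL, on_exit = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  list(name = name, parent = parent, initial = isTRUE(initial),
       parallel = isTRUE(parallel), timer = timer,
       on_entry = on_entry, on_exit = on_exit)
}

#' Declare a transition between two states of a machine
#'
#' @param source,target state names within the same machine.
#' @param trigger event name, or `"timeout"` for the expiry of the source
#'   state's timer.
#' @param guard optional predicate `function(ctx)`; the transition is
#'   enabled only when it returns `TRUE`.
#' @param action optional effect `function(ctx)` run between the exit and
#'   entry phases.
#' @return A transition description used by [sc_machine()].
#' @export
sc_transition <- function(source, target, trigger, guard = NULL,
                          action = NULL) {
  stopifnot(is.character(source), is.character(target),
            is.character(trigger))
  list(source = source, target = target, trigger = trigger,
       guard = guard, action = action)
}

#' Build and validate a statechart machine definition
#'
#' States must form a rooted tree with unique names; every non-parallel
#' composite state needs exactly one initial child; parallel states treat
#' all children as concurrently active regions.  Transitions must connect
#' states of the machine and may not cross between orthogonal regions.
#'
#' @param states list of [sc_state()] descriptions.
#' @param transitions list of [sc_transition()] descriptions.
#' @return An object of class `"sc_machine"`.
#' @export
sc_machine <- function(states, transitions = list()) {
  nms <- vapply(states, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate state names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  st <- stats::setNames(states, nms)
  roots <- nms[vapply(st, function(s) is.null(s$parent), logical(1))]
  if (length(roots) != 1L) {
    stop("machine must have exactly one root state, found ",
         length(roots), call. = FALSE)
  }
  for (s in st) {
    if (!is.null(s$parent) && !s$parent %in% nms) {
      stop("state '", s$name, "' names unknown parent '", s$parent, "'",
           call. = FALSE)
    }
  }
  children <- lapply(st, function(s) character(0))
  for (s in st) {
    if (!is.null(s$parent)) {
      children[[s$parent]] <- c(children[[s$parent]], s$name)
    }
  }
  # reject parent cycles (a cycle never reaches the root)
  depth <- stats::setNames(rep(NA_integer_, length(nms)), nms)
  for (nm in nms) {
    d <- 0L
    cur <- nm
    seen <- character(0)
    while (!is.null(st[[cur]]$parent)) {
      if (cur %in% seen) stop("cycle in state hierarchy at '", nm, "'",
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- st[[cur]]$parent
      d <- d + 1L
      if (d > length(nms)) stop("cycle in state hierarchy", call. = FALSE)
    }
    depth[[nm]] <- d
  }
  initial_child <- stats::setNames(rep(NA_character_, length(nms)), nms)
  for (nm in nms) {
    kids <- children[[nm]]
    if (length(kids) == 0L || st[[nm]]$parallel) next
    ini <- kids[vapply(st[kids], `[[`, logical(1), "initial")]
    if (length(ini) != 1L) {
      stop("composite state '", nm, "' must have exactly one initial child, ",
           "found ", length(ini), call. = FALSE)
    }
    initial_child[[nm]] <- ini
  }
  path_to_root <- function(nm) {
    out <- nm
    while (!is.null(st[[nm]]$parent)) {
      nm <- st[[nm]]$parent
      out <- c(nm, out)
    }
    out
  }
  for (tr in transitions) {
    for (endp in c(tr$source, tr$target)) {
      if (!endp %in% nms) {
        stop("transition references unknown state '", endp, "'",
             call. = FALSE)
      }
    }
    ps <- path_to_root(tr$source)
    pt <- path_to_root(tr$target)
    common <- min(length(ps), length(pt))
    for (k in seq_len(common)) {
      if (ps[k] != pt[k]) break
      if (st[[ps[k]]]$parallel && k < common && ps[k + 1] != pt[k + 1]) {
        stop("transition '", tr$source, "' -> '", tr$target,
             "' crosses orthogonal regions of '", ps[k], "'", call. = FALSE)
      }
    }
  }
  structure(list(states = st, transitions = transitions, root = roots,
                 children = children, depth = depth,
                 initial_child = initial_child),
            class = "sc_machine")
}

#' @export
print.sc_machine <- function(x, ...) {
  cat("<sc_machine> ", length(x$states), " states, ",
      length(x$transitions), " transitions, root '", x$root, "'\n", sep = "")
  invisible(x)
}

sc_enter <- function(inst, nm) {
  spec <- inst$spec
  s <- spec$states[[nm]]
  if (!nm %in% inst$active) { # entry effects only on a real (re-)entry
    inst$active <- union(inst$active, nm)
    if (!is.null(s$on_entry)) s$on_entry(inst$context)
    if (!is.null(s$timer)) inst$timers[[nm]] <- as.integer(s$timer)
  }
  kids <- spec$children[[nm]]
  if (length(kids)) {
    if (s$parallel) {
      for (k in kids) inst <- sc_enter(inst, k)
    } else if (!any(kids %in% inst$active)) {
      inst <- sc_enter(inst, spec$initial_child[[nm]])
    }
  }
  inst
}

sc_exit_subtree <- function(inst, nm) {
  spec <- inst$spec
  doomed <- intersect(inst$active, sc_descendants(spec, nm))
  doomed <- doomed[order(spec$depth[doomed], decreasing = TRUE)] # inner first
  for (d in doomed) {
    s <- spec$states[[d]]
    if (!is.null(s$on_exit)) s$on_exit(inst$context)
    inst$timers[[d]] <- NULL
  }
  inst$active <- setdiff(inst$active, doomed)
  inst
}

sc_descendants <- function(spec, nm) {
  out <- nm
  queue <- spec$children[[nm]]
  while (length(queue)) {
    out <- c(out, queue[1])
    queue <- c(queue[-1], spec$children[[queue[1]]])
  }
  out
}

sc_path <- function(spec, nm) {
  out <- nm
  while (!is.null(spec$states[[nm]]$parent)) {
    nm <- spec$states[[nm]]$parent
    out <- c(nm, out)
  }
  out
}

#' Instantiate a machine
#'
#' Puts a fresh instance in the initial configuration: the root, the chain
#' of initial children below it (all regions of parallel states), with
#' entry timers started.
#'
#' @param spec an [sc_machine()].
#' @param context optional environment holding the agent payload that guards
#'   and actions read and write; a new empty environment by default.
#' @return An object of class `"sc_instance"`.
#' @export
sc_instantiate <- function(spec, context = NULL) {
  stopifnot(inherits(spec, "sc_machine"))
  if (is.null(context)) context <- new.env(parent = emptyenv())
  inst <- structure(list(spec = spec, active = character(0),
                         timers = list(), context = context),
                    class = "sc_instance")
  sc_enter(inst, spec$root)
}

#' Active configuration of an instance
#' @param inst an [sc_instantiate()] instance.
#' @return Character vector of active state names (closed under parents).
#' @export
sc_active <- function(inst) sort(inst$active)

fire_transition <- function(inst, tr) {
  spec <- inst$spec
  ps <- sc_path(spec, tr$source)
  pt <- sc_path(spec, tr$target)
  if (tr$source == tr$target) {
    scope <- tr$source # self-transition: exit and re-enter (timer resets)
  } else {
    k <- 1L
    while (k <= min(length(ps), length(pt)) && ps[k] == pt[k]) k <- k + 1L
    # exit the child-of-LCA subtree on the source side
    scope <- if (k > length(ps)) pt[k] else ps[k]
  }
  inst <- sc_exit_subtree(inst, scope)
  if (!is.null(tr$action)) tr$action(inst$context)
  # enter the inactive part of the target path, outer to inner; completion
  # below the target itself is handled by sc_enter()
  enter_chain <- pt[!pt %in% inst$active]
  for (nm in enter_chain[-length(enter_chain)]) {
    inst$active <- union(inst$active, nm)
    s <- spec$states[[nm]]
    if (!is.null(s$on_entry)) s$on_entry(inst$context)
    if (!is.null(s$timer)) inst$timers[[nm]] <- as.integer(s$timer)
  }
  sc_enter(inst, tr$target)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

enabled_transitions <- function(inst, trigger) {
  keep <- vapply(inst$spec$transitions, function(tr) {
    tr$trigger == trigger && tr$source %in% inst$active &&
      (is.null(tr$guard) || isTRUE(tr$guard(inst$context)))
  }, logical(1))
  inst$spec$transitions[keep]
}

#' Dispatch an event to an instance
#'
#' The enabled transition with the deepest source state fires; ties at the
#' same depth fall back to declaration order, or raise an error when
#' `strict = TRUE`.  With no enabled transition the configuration is
#' returned unchanged.
#'
#' @param inst an [sc_instantiate()] instance.
#' @param event event name.
#' @param strict error on ambiguous same-depth transitions?
#' @return The updated instance.
#' @export
sc_dispatch <- function(inst, event, strict = FALSE) {
  cands <- enabled_transitions(inst, event)
  if (length(cands) == 0L) return(inst)
  depths <- vapply(cands, function(tr) inst$spec$depth[[tr$source]],
                   integer(1))
  top <- which(depths == max(depths))
  if (strict && length(top) > 1L) {
    stop("ambiguous event '", event, "': ", length(top),
         " enabled transitions from depth-", max(depths), " states",
         call. = FALSE)
  }
  fire_transition(inst, cands[[top[1L]]])
}

#' Advance an instance by one tick
#'
#' Decrements the timers of all active timed states; a timer reaching zero
#' fires its state's `"timeout"` transition this tick (deepest source
#' first).  Timers of inactive states do not run, and re-entering a state
#' resets its timer to the full duration.
#'
#' @inheritParams sc_dispatch
#' @return The updated instance.
#' @export
sc_tick <- function(inst) {
  if (length(inst$timers) == 0L) return(inst)
  for (nm in names(inst$timers)) inst$timers[[nm]] <- inst$timers[[nm]] - 1L
  expired <- names(inst$timers)[vapply(inst$timers, function(t) t <= 0L,
                                       logical(1))]
  expired <- expired[order(inst$spec$depth[expired], decreasing = TRUE)]
  for (nm in expired) {
    if (!nm %in% inst$active) next        # an earlier timeout exited it
    if (is.null(inst$timers[[nm]]) || inst$timers[[nm]] > 0L) next # restarted
    inst$timers[[nm]] <- NULL
    cands <- enabled_transitions(inst, "timeout")
    cands <- Filter(function(tr) tr$source == nm, cands)
    if (length(cands)) inst <- fire_transition(inst, cands[[1L]])
  }
  inst
}

#' @export
print.sc_instance <- function(x, ...) {
  cat("<sc_instance> active: {", paste(sc_active(x), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Serialize a machine definition to JSON
#'
#' Writes the states (name, parent, initial/parallel flags, timers) and
#' transitions (source, target, trigger, presence of guard/action) as a JSON
#' document for documentation and export.  Guards and actions are code and
#' serialize as logical flags only.
#'
#' @param spec an [sc_machine()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
sc_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "sc_machine"))
  doc <- list(
    root = spec$root,
    states = lapply(unname(spec$states), function(s) {
      list(name = s$name, parent = s$parent, initial = s$initial,
           parallel = s$parallel, timer = s$timer)
    }),
    transitions = lapply(spec$transitions, function(tr) {
      list(source = tr$source, target = tr$target, trigger = tr$trigger,
           guarded = !is.null(tr$guard), action = !is.null(tr$action))
    })
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
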