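# Shared simulated fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

ctl_fixture <- function() {
  fixture("ctl", function() {
    panel <- panel_config()
    cells <- simulate_population(sim_config(polyQ_length = 25, n_cells = 3000,
                                            time_points = 46, seed = 3))
    list(panel = panel,
         cells = cells,
         events = cells_to_events(cells, panel, seed = 4),
         untransfected = cells_to_events(cells[0, ], panel,
                                         n_untransfected = 2000, seed = 5),
         unstained = cells_to_events(cells[0, ], panel,
                                     n_untransfected = 2000,
                                     stain_sytox = FALSE, seed = 6))
  })
}

q72_fixture <- function() {
  fixture("q72", function() {
    ctl <- ctl_fixture()
    cells <- simulate_population(sim_config(polyQ_length = 72, n_cells = 5000,
                                            time_points = c(18, 46), seed = 11))
    snap <- cells[cells$time == 46, , drop = FALSE]
    events <- cells_to_events(snap, ctl$panel, n_untransfected = 400,
                              n_particles = 250, n_doublets = 80, seed = 12)
    gateset <- derive_gateset(events, ctl$untransfected, ctl$unstained,
                              ctl$events)
    list(cells = cells, snap = snap, events = events, gateset = gateset,
         labels = apply_gates(events, gateset))
  })
}

# gate a freshly simulated arm with the shared controls
gate_arm <- function(Q, arm, n_cells, seed, panel = ctl_fixture()$panel) {
  ctl <- ctl_fixture()
  cells <- simulate_population(sim_config(polyQ_length = Q, n_cells = n_cells,
                                          time_points = 46, arm = arm,
                                          seed = seed))
  snap <- cells[cells$time == 46, , drop = FALSE]
  events <- cells_to_events(snap, panel, seed = seed + 1)
  gs <- derive_gateset(events, ctl$untransfected, ctl$unstained,
                       ctl$events)
  list(cells = cells, snap = snap, events = events,
       labels = apply_gates(events, gs))
}
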