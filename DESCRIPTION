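Package: trajspace
Title: Trajectory-Based Data Management for Parameter Explorations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint management of simulation parameters and results for
    numerical parameter explorations. A trajectory container organises
    typed, lockable parameter and result leaves in a rooted tree with
    natural-naming access and shortcut path resolution; an execution
    environment runs a user model once per explored point in the
    parameter space, serially or on a worker pool, with per-run
    bookkeeping, progress reporting and log files; a storage service
    persists the whole tree one-to-one into a single HDF5 file with
    skeleton-level and lazy on-demand loading. Bundled example models
    (scalar multiplication, elementary cellular automata, a greedy
    stochastic optimizer and a leaky integrate-and-fire network) show
    the intended workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    R6,
    rhdf5,
    parallel,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
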