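Package: aimaze
Title: Active Inference Agent for Maze Exploration and Navigation
Version: 0.1.0
Authors@R: person("Maze", "Forager", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A discrete-state active inference agent that explores and
    navigates grid mazes. Implements a two-modality partially observed
    Markov decision process generative model, variational belief updating
    by damped relaxation to exact per-policy smoothing marginals, policy
    selection by expected free energy (risk, ambiguity and Dirichlet
    novelty), precision (inverse temperature) updating, likelihood
    learning via Dirichlet concentration accumulation, and a
    graph-Laplacian diffusion heuristic that converts a distal goal into
    attainable subgoal preferences. Includes synthetic
    electrophysiological readouts (rasters, local field potentials,
    time-frequency maps, dopamine traces, path/place-cell
    classification), behavioural metrics, a seeded maze generator with a
    breadth-first-search oracle, and a command-line interface for the
    canonical exploration, navigation and goal-directed experiments.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
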