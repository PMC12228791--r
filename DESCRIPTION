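Package: mtmotor
Title: Microtubule Filament Metadata Consensus, Motor-Domain Structure
    Comparison and Adaptive-Seeding MD Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("mtmotor", "developers", email = "mtmotor@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of kinesin-microtubule
    structural studies. Implements per-filament consensus bookkeeping for
    cryo-EM particle metadata in Relion STAR format (modal class voting,
    circular smoothing of in-plane angles and shifts, circular-median phi
    assignment, segment averaging, seam/alpha-beta-register hypothesis
    enumeration and assignment, symmetry expansion and focused sub-particle
    re-centering, motor-state occupancy statistics); quantitative comparison
    of atomic models (Kabsch superposition restricted to named selections,
    per-residue RMSD, C-alpha displacements, inter-head rotation
    decomposition, hydrogen-bond network extraction and diffing); and
    molecular-dynamics trajectory observables (monitored pair distances,
    ligand RMSD after core alignment, fluctuation statistics, adaptive
    restart-frame selection across protocol levels, nucleotide-release
    detection, ion-coordination counting, simulation-time ledgers). A
    synthetic-data module generates filament tables, toy structure pairs and
    Langevin escape trajectories with known ground truth so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
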