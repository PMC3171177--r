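# Bundled example data

All files are plain TSV/CSV. States are integers in `{0, ..., p-1}`.

## `ternary3_series.tsv`

A 3-gene ternary (GF(3)) example time course of four consecutive network
states. Loaded with `read_transitions(..., format = "series", p = 3)` it
yields three transition pairs. Small enough that the full model space (two
distinct minimal polynomial models, two Groebner cones of equal volume) can
be explored exactly; used throughout the tests and the vignette.

## `yeast_cc_transitions_synthetic.tsv`

SYNTHETIC stand-in for a published set of 54 Boolean input/output state
transitions of the 11-regulator yeast cell-cycle network (columns: the 11
regulators with `_in` suffixes, then the same with `_out`). The published
rendering of that table available to us is internally inconsistent
(conflicting duplicate input rows, no steady rows), so this file was
generated once, deterministically, from the standard 11-node cell-cycle
Boolean threshold network - which reproduces the published attractor
structure (7 fixed points, basin sizes 1764/151/109/9/7/7/1) - by recording
basin trajectories: the canonical excited-G1 path plus the deepest
trajectory of each remaining basin, four of them run into their fixed point.
It matches the published data's checkable invariants: 54 distinct consistent
pairs over GF(2), 11 variables, exactly 4 steady pairs.

## `yeast_cc_wiring_synthetic.csv`

SYNTHETIC reference adjacency for the same network (rows = targets, columns
= regulators, 1 where the target's update rule references the regulator,
including each node's own-state memory/decay term). Used to demonstrate
probability-weighted PPV/sensitivity/specificity scoring of inferred
dependency graphs; it is a reconstruction, not the (unpublished) matrix the
original study scored against.
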