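# molfewshot

Few-shot molecular property prediction in R: episodic training of a graph
isomorphism network (GIN) encoder for binary molecular tasks, with a
bifurcated objective that combines supervised cross-entropy with a *dynamic
contrastive loss* whose hard-negative emphasis decays exponentially over
training.

The package is aimed at method developers and computational chemists who
work with MoleculeNet-style multi-task tables (one SMILES column, one
column of 1/0/missing labels per task) where each task has few labelled
compounds and often a severely imbalanced class ratio. Everything runs on
plain CPU R and is fully exercisable with no external downloads through a
synthetic motif-labelled task-family generator.

## The objective

For a batch of embedded molecules with labels, the training loss is

    L = L_label + w * L_contra

where `L_label` is mean cross-entropy over query molecules and

    L_contra = sum over pairs i<j of
               [ y_ij * D_ij^2 + (1 - y_ij) * max(0, m - D_ij^2) ] * I_ij

with `D_ij` the Euclidean distance between pre-head embeddings, `y_ij = 1`
for same-class pairs and margin `m`. The indicator `I_ij` keeps all
same-class (attraction) pairs, but among different-class pairs keeps only
the `ceiling(f(t) * |K|)` closest — the *hard negatives* — where

    f(t) = alpha_start * exp(-beta * t) + alpha_end

decays with the number `t` of completed outer optimization steps (defaults
`alpha_start = 1`, `alpha_end = 0.2`, `beta = 0.01`; the raw `f(0) = 1.2`
is clipped to 1 for selection and both values are logged). Training is a
first-order episodic loop: adapt a parameter clone on each support set,
update the shared parameters from the query loss under Adam. Evaluation
follows the few-shot protocol: per held-out task, fine-tune on a sampled
k-shot support, score the rest, and report rank-based AUC mean ± sd over
repeated seeded runs.

## Worked example

```r
library(molfewshot)

fam <- generate_task_family(synthetic_spec(
  n_tasks = 8, n_molecules_per_task = 100, positive_fraction = 0.2,
  seed = 11, n_test_tasks = 2))

enc <- encoder_config(n_layers = 5, hidden_dim = 32)
lc  <- loss_config(weight_w = 1e-5)   # w absorbs the unnormalised pair-sum scale
mc  <- meta_config(meta_train_iterations = 150, runs = 3)

stream <- episode_stream(fam$table, fam$split, "meta_train",
                         k_shot = 10, seed = 1, n_episodes = 150)
fit <- meta_train(init_encoder_params(enc, 1), stream, lc, mc,
                  training_clock(), enc)
meta_test(fit$params, fam$table, fam$split, 10, lc, mc, enc, fit$state,
          seed = 5)
#> <eval_report> 3 run(s): AUC 0.9519 +/- 0.0174
#>   task_07: 0.9590 (3 run(s), 0 missing)
#>   task_08: 0.9448 (3 run(s), 0 missing)
```

Each of the 8 synthetic tasks hides a 3-heteroatom motif; a molecule is
positive iff it contains the motif as a labelled subgraph. After 150
episodic steps the encoder adapts to the two held-out tasks from 10
molecules per class and ranks the remaining ~130 query molecules at AUC
≈ 0.95 (chance is 0.5). The whole run takes well under a minute on one CPU.

Real data enters through `read_task_table()` (CSV with a `smiles` column
and one 1/0/empty column per task) and `read_task_split()` (JSON with
`train_tasks` / `test_tasks`); `load_checkpoint()` plugs in externally
pretrained encoder trunks, initializing a fresh head when the archive has
none.

## Command line

A thin CLI over the same functions ships in `inst/cli/molfewshot.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/molfewshot.R", package="molfewshot"))')" \
    simulate --config run.yaml
# subcommands: simulate | train | eval | ablate | project
```

The YAML config has sections `data / encoder / loss / episodes / meta /
eval / synthetic` plus a global `seed` and `output_dir`; unknown keys are
rejected. `train` writes a checkpoint and a JSON-lines metrics log (one
line per outer step with component losses and the raw and clipped `f(t)`);
`ablate` compares the `full` / `wc` (no contrastive) / `wd` (no schedule)
variants; `project` writes 2-D PCA scatter plots and silhouette
class-separation scores per test task.

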