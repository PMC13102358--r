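"""Batch coalescent simulation worker.

Reads a JSON job description and writes one JSON line per replicate. The R
package owns all scenario logic (demographic model construction, pulse
parameter draws, encoding); this worker only turns a backward-time event list
into an msprime Demography, runs the ARG + mutation simulation, and extracts
migrant-ancestry tracts from the recorded migration table.

Job schema (all times in generations, sizes diploid):
{
  "demography": {
    "populations": [{"name", "initial_size", "growth_rate"}, ...],
    "migration":   [{"source", "dest", "rate"}, ...],   # backward rates at t=0
    "events": [
      {"type": "size_change", "time", "population", "initial_size",
       "growth_rate"},
      {"type": "migration_change", "time", "source", "dest", "rate"},
      {"type": "split", "time", "derived": [..], "ancestral"}
    ]
  },
  "samples": {"<pop>": n_diploids, ...},
  "mutation_rate": float, "recombination_rate": float,
  "replicates": [
    {"id", "seed", "length",
     "rate_scale": 1.0,              # shared mutation+recombination scaler
     "pulses": [{"recipient", "donor", "proportion", "time"}, ...],
     "min_sites": 128,
     "require_tracts": true,          # >=1 flagged recipient hap per pulse
     "max_attempts": 100}
  ]
}

Output line per replicate:
{"id", "attempts", "positions": [...], "haps": ["0101...", ...],
 "flags": [0/1 ...], "tracts": [{"hap", "left", "right", "donor"}, ...],
 "pop_sizes": [n_hap_pop1, n_hap_pop2]}
Haplotype order: all haplotypes of the first sampled population, then the
second, matching tskit sample order.
"""

import json
import sys

import msprime

MOD = 2 ** 31 - 1


def next_seed(seed, attempt):
    return (seed * 69069 + 12345 * (attempt + 1)) % (MOD - 2) + 1


def build_demography(spec, pulses):
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(
            name=pop["name"],
            initial_size=pop["initial_size"],
            growth_rate=pop.get("growth_rate", 0.0),
        )
    for mig in spec.get("migration", []):
        if mig["rate"] > 0:
            dem.set_migration_rate(
                source=mig["source"], dest=mig["dest"], rate=mig["rate"]
            )
    for ev in spec.get("events", []):
        t = ev["type"]
        if t == "size_change":
            dem.add_population_parameters_change(
                time=ev["time"],
                population=ev["population"],
                initial_size=ev["initial_size"],
                growth_rate=ev.get("growth_rate", 0.0),
            )
        elif t == "migration_change":
            dem.add_migration_rate_change(
                time=ev["time"],
                rate=ev["rate"],
                source=ev["source"],
                dest=ev["dest"],
            )
        elif t == "split":
            dem.add_population_split(
                time=ev["time"], derived=ev["derived"], ancestral=ev["ancestral"]
            )
        else:
            raise ValueError("unknown event type: %s" % t)
    # a pulse moving lineages of the recipient onto the donor backwards in
    # time == forward-time introgression donor -> recipient
    for p in pulses:
        dem.add_mass_migration(
            time=p["time"],
            source=p["recipient"],
            dest=p["donor"],
            proportion=p["proportion"],
        )
    dem.sort_events()
    return dem


def donor_tracts(ts, pulses, pop_id, sample_sets):
    """Per-haplotype donor-ancestry intervals created by the pulses.

    A pulse is recorded as lineages of the recipient moving onto the donor
    backwards in time; each migration record at the pulse time marks a
    lineage whose descendants inherited donor material. Only descendants
    sampled in the *recipient* population are labelled: with background
    migration, a moved lineage can also be ancestral to donor-side samples
    (the haplotype simply persists in the donor), which is not introgression
    into the recipient.
    """
    import numpy as np

    tracts = []
    if not pulses:
        return tracts
    mt = ts.tables.migrations
    if len(mt) == 0:
        return tracts
    sel = np.zeros(len(mt), dtype=bool)
    pulse_of = {}
    for p in pulses:
        key = (p["time"], pop_id[p["donor"]])
        pulse_of[key] = p
        sel |= (mt.time == p["time"]) & (mt.dest == pop_id[p["donor"]])
    idx = np.where(sel)[0]
    if len(idx) == 0:
        return tracts
    nodes = mt.node[idx]
    lefts = mt.left[idx]
    rights = mt.right[idx]
    keys = list(zip(mt.time[idx], mt.dest[idx]))
    recipient_sets = {
        k: frozenset(sample_sets[p["recipient"]]) for k, p in pulse_of.items()
    }
    order = np.argsort(lefts)
    for tree in ts.trees():
        left, right = tree.interval.left, tree.interval.right
        for j in order:
            if rights[j] <= left:
                continue
            if lefts[j] >= right:
                break
            key = keys[j]
            pulse = pulse_of[key]
            rec_set = recipient_sets[key]
            lo, hi = max(left, lefts[j]), min(right, rights[j])
            for s in tree.samples(nodes[j]):
                if s not in rec_set:
                    continue
                tracts.append(
                    {
                        "hap": int(s),
                        "left": float(lo),
                        "right": float(hi),
                        "donor": pulse["donor"],
                    }
                )
    return tracts


def background_tracts(ts, sample_names, pop_id, sample_sets, t_max,
                      pulse_times):
    """Donor-ancestry intervals from continuous (non-pulse) migration.

    Any backward-time move of a lineage into the other population of the
    pair at a time below t_max (the divergence) marks donor-origin material
    in the samples of the opposite population that descend from it. Pulse
    times are excluded (those are labelled by donor_tracts)."""
    import numpy as np

    out = []
    mt = ts.tables.migrations
    if len(mt) == 0:
        return out
    p1, p2 = sample_names[0], sample_names[1]
    ids = {pop_id[p1]: p1, pop_id[p2]: p2}
    sel = (mt.time < t_max) & np.isin(mt.dest, list(ids))
    for t in pulse_times:
        sel &= mt.time != t
    idx = np.where(sel)[0]
    if len(idx) == 0:
        return out
    nodes = mt.node[idx]
    lefts = mt.left[idx]
    rights = mt.right[idx]
    dests = mt.dest[idx]
    order = np.argsort(lefts)
    rec_sets = {
        pop_id[p1]: frozenset(sample_sets[p2]),  # dest p1 -> recipients p2
        pop_id[p2]: frozenset(sample_sets[p1]),
    }
    for tree in ts.trees():
        left, right = tree.interval.left, tree.interval.right
        for j in order:
            if rights[j] <= left:
                continue
            if lefts[j] >= right:
                break
            rec_set = rec_sets[int(dests[j])]
            lo, hi = max(left, lefts[j]), min(right, rights[j])
            for s in tree.samples(nodes[j]):
                if s not in rec_set:
                    continue
                out.append(
                    {
                        "hap": int(s),
                        "left": float(lo),
                        "right": float(hi),
                        "donor": ids[int(dests[j])],
                    }
                )
    return out


def merge_tracts(tracts):
    """Merge abutting/overlapping intervals per (hap, donor) to keep the
    per-tree segmentation from inflating the output."""
    tracts.sort(key=lambda t: (t["hap"], t["donor"], t["left"], t["right"]))
    out = []
    for t in tracts:
        if (
            out
            and out[-1]["hap"] == t["hap"]
            and out[-1]["donor"] == t["donor"]
            and t["left"] <= out[-1]["right"] + 1e-9
        ):
            out[-1]["right"] = max(out[-1]["right"], t["right"])
        else:
            out.append(dict(t))
    return out


def simulate_one(job, rep):
    dem_spec = job["demography"]
    pulses = rep.get("pulses", []) or []
    min_sites = rep.get("min_sites", 1)
    require_tracts = rep.get("require_tracts", True)
    max_attempts = rep.get("max_attempts", 100)
    scale = rep.get("rate_scale", 1.0)
    mut_rate = job["mutation_rate"] * scale
    rec_rate = job["recombination_rate"] * scale

    sample_names = list(job["samples"].keys())
    seed = rep["seed"]
    for attempt in range(max_attempts):
        dem = build_demography(dem_spec, pulses)
        ts = msprime.sim_ancestry(
            samples=job["samples"],
            demography=dem,
            sequence_length=rep["length"],
            recombination_rate=rec_rate,
            record_migrations=bool(pulses) or bool(
                rep.get("background_max_time")
            ),
            random_seed=seed,
        )
        mts = msprime.sim_mutations(
            ts, rate=mut_rate, random_seed=next_seed(seed, 7919)
        )
        pop_id = {p.name: i for i, p in enumerate(dem.populations)}
        sample_sets = {
            name: list(mts.samples(population=pop_id[name]))
            for name in sample_names
        }
        order = [s for name in sample_names for s in sample_sets[name]]

        # biallelic segregating sites only; discrete coordinates can stack
        # mutations at one position -- keep the first site per position
        import numpy as np

        G = mts.genotype_matrix()  # (sites, haps) in ts.samples() order
        pos_all = mts.tables.sites.position.astype(int)
        col_of = {int(s): i for i, s in enumerate(mts.samples())}
        G = G[:, [col_of[int(s)] for s in order]] if G.size else G
        # biallelic and segregating in the sample: both alleles seen, no third
        keep = np.zeros(len(pos_all), dtype=bool)
        if len(pos_all):
            keep = (G.max(axis=1) == 1) & (G.min(axis=1) == 0)
            first = np.ones(len(pos_all), dtype=bool)
            first[1:] = pos_all[1:] != pos_all[:-1]
            keep &= first
        G = G[keep]
        positions = [int(p) for p in pos_all[keep]]

        tracts = merge_tracts(donor_tracts(mts, pulses, pop_id, sample_sets))
        flagged = sorted({t["hap"] for t in tracts})
        bg_tmax = rep.get("background_max_time")
        bg_tracts = (
            merge_tracts(
                background_tracts(
                    mts, sample_names, pop_id, sample_sets, bg_tmax,
                    {p["time"] for p in pulses},
                )
            )
            if bg_tmax
            else []
        )
        ok = len(positions) >= min_sites
        if ok and require_tracts:
            for p in pulses:
                rec_set = set(sample_sets[p["recipient"]])
                if not rec_set.intersection(flagged):
                    ok = False
                    break
        if ok:
            n = len(order)
            rows = ["" for _ in range(n)]
            if len(positions):
                mat = G.T  # (haps, sites)
                codes = (mat.astype(np.uint8) + ord("0")).tobytes()
                step = mat.shape[1]
                rows = [
                    codes[i * step:(i + 1) * step].decode("ascii")
                    for i in range(n)
                ]
            hap_index = {h: i for i, h in enumerate(order)}
            flags = [0] * n
            for t in tracts:
                t["hap"] = hap_index[t["hap"]]
                t["origin"] = "pulse"
                flags[t["hap"]] = 1
            for t in bg_tracts:
                t["hap"] = hap_index[t["hap"]]
                t["origin"] = "background"
            tracts = tracts + bg_tracts
            return {
                "meta": {
                    "id": rep["id"],
                    "attempts": attempt + 1,
                    "n_hap": n,
                    "n_site": len(positions),
                    "flags": flags,
                    "tracts": tracts,
                    "pop_sizes": [
                        len(sample_sets[name]) for name in sample_names
                    ],
                },
                "positions": positions,
                "haps": rows,
            }
        seed = next_seed(seed, attempt)
    raise RuntimeError(
        "replicate %s: no acceptable simulation after %d attempts "
        "(label pulses: %s)" % (rep["id"], max_attempts, pulses)
    )


def main(job_path, out_path):
    """Three lines per replicate: JSON metadata, space-separated positions,
    and all haplotype rows concatenated into one 0/1 string (row-major)."""
    with open(job_path) as fh:
        job = json.load(fh)
    with open(out_path, "w") as out:
        for rep in job["replicates"]:
            res = simulate_one(job, rep)
            out.write(json.dumps(res["meta"]) + "\n")
            out.write(" ".join(str(p) for p in res["positions"]) + "\n")
            out.write("".join(res["haps"]) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
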