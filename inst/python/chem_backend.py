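"""RDKit worker for the pepperm R package.

Invoked as:  python chem_backend.py <request.json> <response.json>

The request is a JSON object {"task": <name>, ...payload}; the response is
a JSON object with an "ok" flag and task-specific fields.  All randomness
is seeded from integers carried in the request, so every task is
deterministic.  Molecules are handled with implicit hydrogens throughout:
nodes, coordinates and surface areas refer to heavy atoms only.
"""

import json
import math
import subprocess
import sys
import tempfile
import os

import numpy as np
from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()

# ---------------------------------------------------------------------------
# small helpers


class ChemError(Exception):
    pass


def mol_from_smiles(smiles, what="molecule"):
    if not isinstance(smiles, str) or smiles.strip() == "":
        raise ChemError("empty SMILES for %s" % what)
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ChemError("unparsable SMILES for %s: %r" % (what, smiles))
    return mol


def stable_hash(*parts):
    """Deterministic 31-bit FNV-1a over the string rendering of parts.

    Mirrors pepperm:::stable_hash() on the R side; both must agree so that
    replica seeds derived in either language coincide.
    """
    h = 2166136261
    for ch in "|".join(str(p) for p in parts):
        h = (h ^ ord(ch)) * 16777619 % 4294967296
    return h % 2147483647


# ---------------------------------------------------------------------------
# parsing / atom tables

HYB_NAMES = {
    Chem.HybridizationType.SP: "sp",
    Chem.HybridizationType.SP2: "sp2",
    Chem.HybridizationType.SP3: "sp3",
}

CHI_NAMES = {
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "cw",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "ccw",
}


def atom_table(mol):
    atoms = {
        "symbol": [], "degree": [], "num_h": [], "charge": [],
        "hybridization": [], "chirality": [], "in_ring": [], "aromatic": [],
    }
    for a in mol.GetAtoms():
        atoms["symbol"].append(a.GetSymbol())
        atoms["degree"].append(a.GetDegree())
        atoms["num_h"].append(a.GetTotalNumHs())
        atoms["charge"].append(a.GetFormalCharge())
        atoms["hybridization"].append(HYB_NAMES.get(a.GetHybridization(), "other"))
        atoms["chirality"].append(CHI_NAMES.get(a.GetChiralTag(), "none"))
        atoms["in_ring"].append(int(a.IsInRing()))
        atoms["aromatic"].append(int(a.GetIsAromatic()))
    return atoms


def bond_table(mol):
    bonds = {"i": [], "j": [], "order": [], "aromatic": [], "conjugated": []}
    for b in mol.GetBonds():
        bonds["i"].append(b.GetBeginAtomIdx())
        bonds["j"].append(b.GetEndAtomIdx())
        bonds["order"].append(b.GetBondTypeAsDouble())
        bonds["aromatic"].append(int(b.GetIsAromatic()))
        bonds["conjugated"].append(int(b.GetIsConjugated()))
    return bonds


def parse_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    n_frags = len(Chem.GetMolFrags(mol))
    return {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "n_heavy": mol.GetNumAtoms(),
        "n_frags": n_frags,
        "atoms": atom_table(mol),
        "bonds": bond_table(mol),
    }


# ---------------------------------------------------------------------------
# macrocycle division and capping


def macrocycle_ring(mol, min_ring):
    info = mol.GetRingInfo()
    best = None
    for ring in info.AtomRings():
        if len(ring) >= min_ring and (best is None or len(ring) > len(best)):
            best = ring
    return best


def cleavable_ring_bonds(mol, ring):
    """Backbone amide C(=O)-N and ester C(=O)-O bonds inside the ring.

    Returns a list of (bond_idx, acyl_c, hetero) with hetero the N/O atom.
    """
    ring_set = set(ring)
    out = []
    for b in mol.GetBonds():
        a1, a2 = b.GetBeginAtom(), b.GetEndAtom()
        if a1.GetIdx() not in ring_set or a2.GetIdx() not in ring_set:
            continue
        if b.GetBondType() != Chem.BondType.SINGLE:
            continue
        for c, x in ((a1, a2), (a2, a1)):
            if c.GetSymbol() != "C" or x.GetSymbol() not in ("N", "O"):
                continue
            has_carbonyl = any(
                nb.GetSymbol() == "O"
                and mol.GetBondBetweenAtoms(c.GetIdx(), nb.GetIdx()).GetBondType()
                == Chem.BondType.DOUBLE
                for nb in c.GetNeighbors()
            )
            if has_carbonyl:
                out.append((b.GetIdx(), c.GetIdx(), x.GetIdx()))
                break
    return out


def cap_fragment_mol(frag):
    """Apply capping chemistry to a fragment carrying [*] end markers.

    A dummy bonded to N or O (the amine / ester side of a cut) becomes a
    methyl carbon; a dummy bonded to an acyl carbon is deleted so the
    carboxyl carbon is left as an aldehyde (implicit H).
    """
    rw = Chem.RWMol(frag)
    to_remove = []
    for atom in rw.GetAtoms():
        if atom.GetAtomicNum() != 0:
            continue
        nbs = atom.GetNeighbors()
        if len(nbs) != 1:
            raise ChemError("end marker with %d neighbours" % len(nbs))
        nb = nbs[0]
        if nb.GetSymbol() in ("N", "O"):
            atom.SetAtomicNum(6)
            atom.SetIsotope(0)
            atom.SetNoImplicit(False)
            atom.SetNumExplicitHs(0)
        elif nb.GetSymbol() == "C":
            to_remove.append(atom.GetIdx())
        else:
            raise ChemError("end marker on unexpected atom %s" % nb.GetSymbol())
    for idx in sorted(to_remove, reverse=True):
        rw.RemoveAtom(idx)
    out = rw.GetMol()
    Chem.SanitizeMol(out)
    return out


def divide_one(job, min_ring=9):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    n_parent = mol.GetNumAtoms()
    ring = macrocycle_ring(mol, min_ring)
    if ring is None:
        raise ChemError("no macrocycle of size >= %d" % min_ring)
    cuts = cleavable_ring_bonds(mol, ring)
    if len(cuts) < 2:
        raise ChemError("fewer than two backbone amide/ester bonds in macrocycle")
    bond_ids = [c[0] for c in cuts]
    frag_mol = Chem.FragmentOnBonds(mol, bond_ids, addDummies=True)
    frag_sets = Chem.GetMolFrags(frag_mol)
    frags = Chem.GetMolFrags(frag_mol, asMols=True, sanitizeFrags=False)

    units = []
    for atom_ids, fm in zip(frag_sets, frags):
        parent_ids = sorted(i for i in atom_ids if i < n_parent)
        Chem.SanitizeMol(fm)
        capped = cap_fragment_mol(fm)
        units.append({"atom_indices": parent_ids, "capped_smiles": Chem.MolToSmiles(capped)})

    # cyclic order: successor of a unit is the unit holding the N/O of the
    # cut whose acyl carbon it contains; start at the unit with the atom of
    # lowest canonical rank, then walk N -> C around the macrocycle.
    owner = {}
    for u, unit in enumerate(units):
        for idx in unit["atom_indices"]:
            owner[idx] = u
    succ = {}
    for _, acyl_c, hetero in cuts:
        succ[owner[acyl_c]] = owner[hetero]
    if len(succ) != len(units):
        raise ChemError("division produced a non-cyclic unit graph")
    ranks = list(Chem.CanonicalRankAtoms(mol))
    start_atom = ranks.index(min(ranks))
    order = [owner[start_atom]]
    while len(order) < len(units):
        nxt = succ[order[-1]]
        if nxt in order:
            raise ChemError("division produced a non-cyclic unit graph")
        order.append(nxt)
    ordered = [units[u] for u in order]
    for pos, unit in enumerate(ordered):
        unit["position"] = pos
    return {"ok": True, "units": ordered}


def cap_one(job):
    frag = mol_from_smiles(job["smiles"], "fragment")
    capped = cap_fragment_mol(frag)
    return {"ok": True, "capped_smiles": Chem.MolToSmiles(capped)}


# ---------------------------------------------------------------------------
# conformers

EMBED_PARAMS = {
    "etdg": AllChem.ETDG,
    "etkdg": AllChem.ETKDG,
    "etkdgv2": AllChem.ETKDGv2,
    "etkdgv3": AllChem.ETKDGv3,
}


def embed_conformer(mol, seed, uff_iters=200, retries=5, method="etdg"):
    """One seeded distance-geometry embedding + UFF minimization.

    Returns (molecule copy, Nx3 heavy-atom coordinate array).  Retries with
    perturbed seeds and a random-coordinate fallback keep the runtime
    bounded on pathological macrocycles.
    """
    work = Chem.Mol(mol)
    cid = -1
    for attempt in range(max(1, retries)):
        params = EMBED_PARAMS.get(method, AllChem.ETDG)()
        params.randomSeed = int(seed + 7919 * attempt)
        params.useRandomCoords = attempt >= 2
        cid = AllChem.EmbedMolecule(work, params)
        if cid == 0:
            break
    if cid != 0:
        raise ChemError("conformer embedding failed after %d attempts" % retries)
    if uff_iters > 0:
        try:
            AllChem.UFFOptimizeMolecule(work, maxIters=int(uff_iters))
        except Exception:
            pass
    conf = work.GetConformer()
    xyz = np.array([[conf.GetAtomPosition(i).x,
                     conf.GetAtomPosition(i).y,
                     conf.GetAtomPosition(i).z] for i in range(work.GetNumAtoms())])
    if not np.all(np.isfinite(xyz)):
        raise ChemError("non-finite coordinates from embedding")
    return work, xyz


def conformers_one(job, uff_iters=200, retries=5, method="etdg"):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    n = int(job["n"])
    base = int(job["base_seed"])
    coords, seeds = [], []
    for k in range(n):
        _, xyz = embed_conformer(mol, base + k, uff_iters, retries, method)
        coords.append([[round(v, 6) for v in row] for row in xyz.tolist()])
        seeds.append(base + k)
    return {"ok": True, "coords": coords, "seeds": seeds}


def sdf_task(req):
    """Write conformers of one molecule to an SDF file (one record each)."""
    mol = mol_from_smiles(req["smiles"], req.get("id", "?"))
    path = req["path"]
    writer = Chem.SDWriter(path)
    for k, (xyz, seed) in enumerate(zip(req["coords"], req["seeds"])):
        m = Chem.Mol(mol)
        conf = Chem.Conformer(m.GetNumAtoms())
        for i, (x, y, z) in enumerate(xyz):
            conf.SetAtomPosition(i, (float(x), float(y), float(z)))
        m.AddConformer(conf, assignId=True)
        m.SetProp("_Name", "%s_conf%d" % (req.get("id", "mol"), k))
        m.SetProp("parent_id", str(req.get("id", "mol")))
        m.SetProp("seed", str(seed))
        writer.write(m)
    writer.close()
    return {"ok": True, "path": path}


# ---------------------------------------------------------------------------
# surface areas, charges, descriptors

_SPHERE_CACHE = {}


def unit_sphere(n=96):
    """Deterministic golden-spiral points on the unit sphere."""
    if n not in _SPHERE_CACHE:
        k = np.arange(n) + 0.5
        phi = np.arccos(1.0 - 2.0 * k / n)
        theta = math.pi * (1.0 + math.sqrt(5.0)) * k
        _SPHERE_CACHE[n] = np.column_stack(
            (np.cos(theta) * np.sin(phi), np.sin(theta) * np.sin(phi), np.cos(phi)))
    return _SPHERE_CACHE[n]


def shrake_rupley(xyz, radii, probe=1.4, n_points=96):
    """Per-atom solvent-accessible surface area (A^2), heavy atoms only."""
    pts = unit_sphere(n_points)
    rr = np.asarray(radii) + probe
    out = np.zeros(len(radii))
    for i in range(len(radii)):
        sphere = xyz[i] + rr[i] * pts
        free = np.ones(n_points, dtype=bool)
        for j in range(len(radii)):
            if j == i:
                continue
            d2 = np.sum((sphere - xyz[j]) ** 2, axis=1)
            free &= d2 > rr[j] ** 2
        out[i] = 4.0 * math.pi * rr[i] ** 2 * free.mean()
    return out


def gasteiger_charges(mol):
    AllChem.ComputeGasteigerCharges(mol)
    q = []
    for a in mol.GetAtoms():
        qa = float(a.GetProp("_GasteigerCharge"))
        qh = float(a.GetProp("_GasteigerHCharge")) if a.HasProp("_GasteigerHCharge") else 0.0
        if not (math.isfinite(qa) and math.isfinite(qh)):
            qa, qh = 0.0, 0.0
        q.append(qa + qh)
    return np.array(q)


def vdw_radii(mol):
    return [PT.GetRvdw(a.GetAtomicNum()) for a in mol.GetAtoms()]


def additive_vdw_volume(mol):
    """Sum of atomic van der Waals sphere volumes, implicit H included."""
    vol = 0.0
    r_h = PT.GetRvdw(1)
    for a in mol.GetAtoms():
        vol += 4.0 / 3.0 * math.pi * PT.GetRvdw(a.GetAtomicNum()) ** 3
        vol += a.GetTotalNumHs() * 4.0 / 3.0 * math.pi * r_h ** 3
    return vol


_OBABEL_LOGP_CACHE = {}


def obabel_logp(smiles_list):
    """Octanol/water logP from OpenBabel's additive model (distinct from
    the Wildman-Crippen estimate).  Falls back to Wildman-Crippen when the
    obabel executable is unavailable."""
    todo = [s for s in smiles_list if s not in _OBABEL_LOGP_CACHE]
    if todo:
        try:
            with tempfile.TemporaryDirectory() as td:
                smi = os.path.join(td, "in.smi")
                with open(smi, "w") as fh:
                    for i, s in enumerate(todo):
                        fh.write("%s m%d\n" % (s, i))
                res = subprocess.run(
                    ["obabel", smi, "-otxt", "--append", "logP"],
                    capture_output=True, text=True, timeout=600)
                lines = [l for l in res.stdout.splitlines() if l.strip()]
                if len(lines) != len(todo):
                    raise RuntimeError("obabel row mismatch")
                for s, line in zip(todo, lines):
                    _OBABEL_LOGP_CACHE[s] = float(line.split()[-1])
        except Exception:
            for s in todo:
                _OBABEL_LOGP_CACHE[s] = Crippen.MolLogP(mol_from_smiles(s))
    return [_OBABEL_LOGP_CACHE[s] for s in smiles_list]


DESC16_NAMES = [
    "VSA_EState9", "density", "MolLogP", "fr_Al_OH", "logP_ow",
    "lip_violation", "h_logD", "dens3D", "FNSA4", "RNCS", "FASA_neg",
    "FCASA_pos", "FASA_P", "FNSA2", "FNSA5", "Wp2",
]

_SMARTS_ACID = Chem.MolFromSmarts("C(=O)[OX2H1]")
_SMARTS_BASE = Chem.MolFromSmarts("[NX3;H2,H1;!$(NC=O);!$(N=*);!$(Na)]")


def cpsa_family(mol, xyz):
    q = gasteiger_charges(mol)
    sa = shrake_rupley(np.asarray(xyz, dtype=float), vdw_radii(mol))
    tot = sa.sum()
    neg = q < 0
    pos = q > 0
    polar = np.array([a.GetSymbol() in ("N", "O") for a in mol.GetAtoms()])
    n_neg = max(1, int(neg.sum()))
    sum_qneg = q[neg].sum()  # <= 0
    pnsa2 = sum_qneg * sa[neg].sum()
    pnsa4 = float((q[neg] * sa[neg]).sum()) / n_neg
    pnsa5 = (sum_qneg / n_neg) * sa[neg].sum()
    if neg.any():
        i_mneg = int(np.argmin(q))
        rncg = q[i_mneg] / sum_qneg if sum_qneg != 0 else 0.0
        rncs = sa[i_mneg] * rncg
    else:
        rncs = 0.0
    return {
        "FNSA2": pnsa2 / tot,
        "FNSA4": pnsa4 / tot,
        "FNSA5": pnsa5 / tot,
        "RNCS": rncs,
        "FASA_neg": sa[neg].sum() / tot,
        "FCASA_pos": float((q[pos] * sa[pos]).sum()) / tot,
        "FASA_P": sa[polar].sum() / tot,
    }


def polar_volume(mol):
    vol = 0.0
    r_h = PT.GetRvdw(1)
    for a in mol.GetAtoms():
        if a.GetSymbol() in ("N", "O"):
            vol += 4.0 / 3.0 * math.pi * PT.GetRvdw(a.GetAtomicNum()) ** 3
            vol += a.GetTotalNumHs() * 4.0 / 3.0 * math.pi * r_h ** 3
    return vol


def mol_with_coords(mol, xyz):
    m = Chem.Mol(mol)
    conf = Chem.Conformer(m.GetNumAtoms())
    for i, (x, y, z) in enumerate(xyz):
        conf.SetAtomPosition(i, (float(x), float(y), float(z)))
    m.RemoveAllConformers()
    m.AddConformer(conf, assignId=True)
    return m


def descriptors16(mol, xyz, smiles_for_ob=None):
    if len(xyz) != mol.GetNumAtoms():
        raise ChemError("coordinate rows do not match heavy-atom count")
    mw = Descriptors.MolWt(mol)
    mol3d = mol_with_coords(mol, xyz)
    try:
        vol3d = AllChem.ComputeMolVolume(mol3d)
    except Exception:
        vol3d = additive_vdw_volume(mol)
    logp = Crippen.MolLogP(mol)
    hbd = Lipinski.NumHDonors(mol)
    hba = Lipinski.NumHAcceptors(mol)
    lip = int(mw > 500) + int(logp > 5) + int(hbd > 5) + int(hba > 10)
    n_ion = len(mol.GetSubstructMatches(_SMARTS_ACID)) + \
        len(mol.GetSubstructMatches(_SMARTS_BASE))
    ob_logp = obabel_logp([smiles_for_ob or Chem.MolToSmiles(mol)])[0]
    cpsa = cpsa_family(mol, xyz)
    vals = {
        "VSA_EState9": Descriptors.VSA_EState9(mol),
        "density": mw / additive_vdw_volume(mol),
        "MolLogP": logp,
        "fr_Al_OH": Descriptors.fr_Al_OH(mol),
        "logP_ow": ob_logp,
        "lip_violation": lip,
        "h_logD": logp - 2.0 * n_ion,
        "dens3D": mw / vol3d,
        "Wp2": polar_volume(mol),
    }
    vals.update(cpsa)
    out = [float(vals[k]) for k in DESC16_NAMES]
    if not all(math.isfinite(v) for v in out):
        bad = [k for k, v in zip(DESC16_NAMES, out) if not math.isfinite(v)]
        raise ChemError("non-finite descriptor(s): %s" % ", ".join(bad))
    return out


def descriptor_pool(mol, xyz):
    """A >=100-descriptor pool (2D RDKit set + 3D shape/CPSA) with tags."""
    names, values, tags = [], [], []
    for name, fn in Descriptors.descList:
        if name.startswith("Ipc"):  # numerically explosive on macrocycles
            continue
        try:
            v = float(fn(mol))
        except Exception:
            v = float("nan")
        names.append(name)
        values.append(v if math.isfinite(v) else 0.0)
        tags.append("2D")
    mol3d = mol_with_coords(mol, xyz)
    threed = {
        "Asphericity": rdMolDescriptors.CalcAsphericity,
        "Eccentricity": rdMolDescriptors.CalcEccentricity,
        "InertialShapeFactor": rdMolDescriptors.CalcInertialShapeFactor,
        "NPR1": rdMolDescriptors.CalcNPR1,
        "NPR2": rdMolDescriptors.CalcNPR2,
        "PMI1": rdMolDescriptors.CalcPMI1,
        "PMI2": rdMolDescriptors.CalcPMI2,
        "PMI3": rdMolDescriptors.CalcPMI3,
        "RadiusOfGyration": rdMolDescriptors.CalcRadiusOfGyration,
        "SpherocityIndex": rdMolDescriptors.CalcSpherocityIndex,
        "PBF": rdMolDescriptors.CalcPBF,
    }
    for name, fn in threed.items():
        try:
            v = float(fn(mol3d))
        except Exception:
            v = 0.0
        names.append(name)
        values.append(v)
        tags.append("3D")
    for name, v in cpsa_family(mol, xyz).items():
        names.append("CPSA_" + name)
        values.append(float(v))
        tags.append("3D")
    return {"names": names, "values": values, "tags": tags}


def fingerprint_bits(mol):
    """2048 bits: 1024 at radius 2 followed by 1024 at radius 3 (on-bit ids)."""
    fp2 = AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=1024)
    fp3 = AllChem.GetMorganFingerprintAsBitVect(mol, 3, nBits=1024)
    return sorted(list(fp2.GetOnBits()) + [1024 + b for b in fp3.GetOnBits()])


def synthprops_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    return {
        "ok": True,
        "MolLogP": Crippen.MolLogP(mol),
        "TPSA": rdMolDescriptors.CalcTPSA(mol),
        "NumHDonors": Lipinski.NumHDonors(mol),
        "MolWt": Descriptors.MolWt(mol),
    }


# ---------------------------------------------------------------------------
# SMILES enumeration


def enumerate_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    n = int(job["n"])
    rng = np.random.RandomState(int(job["seed"]) % 2147483647)
    out = []
    for _ in range(n):
        perm = rng.permutation(mol.GetNumAtoms()).tolist()
        out.append(Chem.MolToSmiles(Chem.RenumberAtoms(mol, perm), canonical=False))
    return {"ok": True, "smiles": out}


# ---------------------------------------------------------------------------
# batched featurization for model input


def featurize_task(req):
    """Full multi-level featurization of a set of peptides.

    For each record and replica index k the atom ordering, peptide conformer
    and monomer conformers are all derived from seeds hashed out of
    (run_seed, id or monomer SMILES, k), so the output depends only on the
    request content.  Monomer descriptor vectors are cached per
    (capped_smiles, k): identical monomers share conformers across peptides.
    """
    run_seed = int(req["seed"])
    replicas = int(req["replicas"])
    uff_iters = int(req.get("uff_iters", 200))
    retries = int(req.get("retries", 5))
    method = req.get("method", "etdg")
    mono_cache = {}
    out_records = []
    for rec in req["records"]:
        mol = mol_from_smiles(rec["smiles"], rec.get("id", "?"))
        fp = fingerprint_bits(mol)
        reps = []
        for k in range(replicas):
            rep_seed = stable_hash(run_seed, rec["id"], k)
            rng = np.random.RandomState(rep_seed % 2147483647)
            perm = rng.permutation(mol.GetNumAtoms()).tolist()
            smiles_k = Chem.MolToSmiles(Chem.RenumberAtoms(mol, perm),
                                        canonical=False)
            # re-parse so atom tables, coordinates and descriptors all
            # follow the replica SMILES string's written atom order
            mol_k = mol_from_smiles(smiles_k, "replica")
            _, xyz = embed_conformer(mol_k, rep_seed % 100000, uff_iters, retries, method)
            desc = descriptors16(mol_k, xyz, smiles_for_ob=rec["smiles"])
            mono_rows = []
            for msmi in rec.get("monomers", []):
                key = (msmi, k)
                if key not in mono_cache:
                    mmol = mol_from_smiles(msmi, "monomer")
                    mseed = stable_hash(run_seed, msmi, k)
                    _, mxyz = embed_conformer(mmol, mseed % 100000, uff_iters, retries, method)
                    mono_cache[key] = descriptors16(mmol, mxyz, smiles_for_ob=msmi)
                mono_rows.append(mono_cache[key])
            reps.append({
                "smiles": smiles_k,
                "atoms": atom_table(mol_k),
                "bonds": bond_table(mol_k),
                "coords": [[round(v, 6) for v in row] for row in xyz.tolist()],
                "desc16": desc,
                "monomer_desc": mono_rows,
            })
        out_records.append({"id": rec["id"], "fp_bits": fp, "replicas": reps})
    return {"ok": True, "records": out_records, "desc_names": DESC16_NAMES}


# ---------------------------------------------------------------------------
# dispatch


def run_jobs(jobs, fn, **kw):
    out = []
    for job in jobs:
        try:
            out.append(fn(job, **kw))
        except ChemError as e:
            out.append({"ok": False, "error": str(e)})
        except Exception as e:  # pragma: no cover - defensive
            out.append({"ok": False, "error": "%s: %s" % (type(e).__name__, e)})
    return out


def descriptors16_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    vals = descriptors16(mol, job["coords"], smiles_for_ob=job["smiles"])
    return {"ok": True, "names": DESC16_NAMES, "values": vals}


def pool_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    res = descriptor_pool(mol, job["coords"])
    res["ok"] = True
    return res


def fingerprint_one(job):
    mol = mol_from_smiles(job["smiles"], job.get("id", "?"))
    return {"ok": True, "bits_on": fingerprint_bits(mol)}


def main():
    req_path, res_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    task = req.get("task")
    try:
        if task == "parse":
            res = {"ok": True, "results": run_jobs(req["jobs"], parse_one)}
        elif task == "divide":
            res = {"ok": True, "results": run_jobs(
                req["jobs"], divide_one, min_ring=int(req.get("min_ring", 9)))}
        elif task == "cap":
            res = {"ok": True, "results": run_jobs(req["jobs"], cap_one)}
        elif task == "conformers":
            res = {"ok": True, "results": run_jobs(
                req["jobs"], conformers_one,
                uff_iters=int(req.get("uff_iters", 200)),
                retries=int(req.get("retries", 5)),
                method=req.get("method", "etdg"))}
        elif task == "sdf":
            res = sdf_task(req)
        elif task == "descriptors16":
            res = {"ok": True, "results": run_jobs(req["jobs"], descriptors16_one)}
        elif task == "pool":
            res = {"ok": True, "results": run_jobs(req["jobs"], pool_one)}
        elif task == "fingerprint":
            res = {"ok": True, "results": run_jobs(req["jobs"], fingerprint_one)}
        elif task == "enumerate":
            res = {"ok": True, "results": run_jobs(req["jobs"], enumerate_one)}
        elif task == "synthprops":
            res = {"ok": True, "results": run_jobs(req["jobs"], synthprops_one)}
        elif task == "featurize":
            res = featurize_task(req)
        else:
            res = {"ok": False, "error": "unknown task: %r" % task}
    except Exception as e:
        res = {"ok": False, "error": "%s: %s" % (type(e).__name__, e)}
    with open(res_path, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
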