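# Reference structures (not redistributed)

The geometry checks against published structures need PDB files that this
package does not ship. With network access, deposit them here:

    3vub.pdb   CcdB crystal structure (dimer)
    3ze5.pdb   DgkA crystal structure (trimer)
    2kdc.pdb   DgkA solution-NMR ensemble (16 poses)

e.g. `curl -O https://files.rcsb.org/download/3VUB.pdb` (rename to
lower case). The decoy archive (doi:10.5061/dryad.3g092) goes into a
sibling `decoys/` directory as individual PDB files. The test suite and
the worked examples pick them up automatically; without them the
corresponding checks report the files as missing.
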