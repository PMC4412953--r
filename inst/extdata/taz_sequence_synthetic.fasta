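>TAZ_synthetic synthetic tafazzin-like construct (not the biological sequence)
MASTPQLLVALLAGVLLIPLVVAFGLLSGTPQSNTSGSQNSLTAGQVNPLYLTIGQRNPS
SPTAGQVNHSSLTDGQVNPGSLTAGQVNPSSLTRGQVNPSDLTFGKVNPSSLTAGGKCVS
SLRGESPFKEDSGQEKSDNEQKSPEKDGSEQKDSGQVNPSGLTAGQVNLSSLTWGQVFPS
SLVAGQKNPSSLTAGQGNPSSLTAGQVNILSLTHGGVNPSSLTAGQVNPSSLRAGQVNPG
SLTAGQVNPSSLTAGQVNPSSLTAGQVNPSSLTAGQVNPSSLTAGQVNPSSL
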