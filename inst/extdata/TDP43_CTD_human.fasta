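>TDP43_CTD_human residues 267-414 of human TDP43 (UniProtKB Q13148)
NRQLERSGRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGSNMGGGMNFGAFSINPAMMAAA
QAALQSSWGMMGMLASQQNQSGPSGNNQNQGNMQREPNQAFGSGNNSYSGSNSGAAIGWG
SASNAGSGSGFNGGFGSSMDSKSSGWGM
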