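virus_id,genus,family,morphology,own_host
HRTV-10,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. B2-2
HRTV-18,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS10-3
HRTV-20,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS10-9
HRTV-22,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS10-9
HRTV-26,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS10-9
HRTV-5,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. s5a-3
HCTV-7,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-12,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-9,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-11,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula californiae
HRTV-9,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. B2-2
HRTV-16,Haloferacalesvirus,Hafunaviridae,myovirus,Haloterrigena sp. SS13-7
HCTV-8,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-10,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sodomense
HJTV-1,Haloferacalesvirus,Hafunaviridae,myovirus,Haloarcula japonica
HRTV-13,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS8-2
HRTV-21,Haloferacalesvirus,Hafunaviridae,myovirus,Halorubrum sp. SS10-9
HSTV-2,Mincapvirus,Hafunaviridae,myovirus,Halorubrum sodomense
HRTV-7,Mincapvirus,Hafunaviridae,myovirus,Halorubrum sp. B2-2
HRTV-2,Mincapvirus,Hafunaviridae,myovirus,Halorubrum sp. s1-2
HRTV-11,Mincapvirus,Hafunaviridae,myovirus,Halorubrum sp. SL-5
HCTV-6,Mincapvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-13,Mincapvirus,Hafunaviridae,myovirus,Haloarcula californiae
HCTV-15,Mincapvirus,Hafunaviridae,myovirus,Halorubrum sp. SS6-2
HFTV1,Retbasiphovirus,Haloferuviridae,siphovirus,Haloferax gibbonsii LR2-5
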