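column,type,units,description
record_id,string,,unique identifier of the study-record
species_id,string,,species identifier; must appear in the species table and the phylogeny tip labels
y,integer or empty,count,number of samples containing the item; empty cell = frequency not reported
N,integer,count,sample size of the record (>= 1)
mentioned,0/1,,1 when the source mentions the item without quantifying it; only valid on rows with empty y
sample_type,0/1,,0 = scat 1 = digestive tract
island,0/1,,1 when the sampling site is an island (excluding large islands)
spring,0/1,,study season flag; all six season flags may be 0 for whole-year studies
summer,0/1,,study season flag
autumn,0/1,,study season flag
winter,0/1,,study season flag
dry,0/1,,study season flag
wet,0/1,,study season flag
precip,numeric,mm,mean monthly precipitation before min-max normalization
tmax,numeric,deg C,mean daily maximum temperature
tmin,numeric,deg C,mean daily minimum temperature
ndvi,numeric,unitless,mean monthly NDVI in [-1 1]
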