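scan_id,nodule_id,reader_id,subtlety,internal_structure,calcification,sphericity,margin,lobulation,spiculation,texture,malignancy,diameter_mm,centre_z,centre_y,centre_x
s1,n1,r1,3,1,5,4,4,2,2,5,1,8,16,16,16
s1,n1,r2,3,1,5,4,4,2,2,5,2,8,16,16,16
s1,n1,r3,3,1,5,4,NA,2,2,5,2,8,16,16,16
s1,n1,r4,3,1,5,4,4,2,2,5,1,8,16,16,16
s1,n2,r1,3,1,5,4,4,2,2,5,1,5,16,16,16
s1,n2,r2,3,1,5,4,4,2,2,5,1,5,16,16,16
s1,n2,r3,3,1,5,4,4,2,2,5,2,5,16,16,16
s2,n3,r1,3,1,5,4,4,4,5,5,5,15,16,16,16
s2,n3,r2,3,1,5,4,4,4,5,5,4,15,16,16,16
s2,n3,r3,3,1,5,4,4,4,5,5,4,15,16,16,16
s2,n3,r4,3,1,5,4,4,4,5,5,5,15,16,16,16
s2,n4,r1,4,1,5,4,4,2,2,5,4,12,16,16,16
s2,n4,r2,2,1,5,4,4,2,2,5,4,12,16,16,16
s2,n4,r3,3,1,5,4,4,2,2,5,5,12,16,16,16
s3,n5,r1,3,1,5,4,4,2,2,5,3,6,16,16,16
s3,n5,r2,3,1,5,4,4,2,2,5,3,6,16,16,16
s3,n5,r3,3,1,5,4,4,2,2,5,3,6,16,16,16
s3,n6,r1,3,1,5,4,4,2,2,5,4,2.5,16,16,16
s3,n6,r2,3,1,5,4,4,2,2,5,5,2.5,16,16,16
s3,n6,r3,3,1,5,4,4,2,2,5,4,2.5,16,16,16
s3,n6,r4,3,1,5,4,4,2,2,5,4,2.5,16,16,16
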